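# airtherm

Simulation and recognition toolkit for airflow-driven thermoelectric
sensing of physiological signals.

Wearable thermoelectric devices (TEDs) convert the temperature difference
between their skin-facing and air-facing surfaces into a voltage via the
Seebeck effect, `V = α·ΔT`.  Breathing, speech bursts and coughs all blow
air of characteristic speed and temperature over the device, changing that
temperature difference by convective heat transfer — so the voltage trace
carries a readable imprint of respiration, speech and cough activity.
`airtherm` is for researchers who want to study that sensing principle
quantitatively without hardware: it provides the forward model from
airflow to voltage, a thermocouple-level solver for velocity-sweep
studies, seeded synthetic physiological signal generators, and the
downstream recognition layers (cough alarm, speech classification, and
multi-source abnormal-state detection from airflow + heartbeat).

## The model

For laminar flow over the flat air-facing surface, the average convective
coefficient follows the flat-plate Nusselt correlation

    h = (κ/L)·Nu = 0.664·(κ/L)·Re^(1/2)·Pr^(1/3),    Re = ρ v L / μ,

the air-facing surface is a lumped thermal mass obeying Newton cooling,

    m·c_p·dT_upper/dt = h(v)·A·(T_air − T_upper),

and the device reads out `V = α·(T_upper − T_lower)`.  For constant
airflow the closed-form response is an exponential approach,
`T_upper(t) = T_air − (T_air − T_upper(0))·e^(−f t)` with
`f = h·A/(m·c_p)`; for time-varying airflow the integrator applies that
exponential exactly over each sampling interval.  A 1-D steady-state
solver for the coupled thermoelectric field (energy with Joule source,
current continuity, generalized Ohm's law) with a convective upper
boundary handles the per-leg/per-couple physics, using the published
material constants (α_p = 202.5 µV/K, α_n = −210 µV/K, ...).

On top of the forward model sit: short-time Fourier spectral features, a
contrast-normalized cough detector with a ≥3-severe-coughs-in-5-s alarm
rule, a fully-connected speech classifier (9 train / 1 test per class),
and a gradient-boosted fusion classifier that labels a recording abnormal
iff the airflow channel is abnormal (distress speech, feeble or
weightless respiration) **and** the heartbeat channel is abnormal.

## Worked example

```r
library(airtherm)

air <- fluidProperties()                 # κ = 0.0257 W/(m K), air at ~20 °C
convectiveCoefficient(air, L = 0.01, v = 1)
#> [1] 39.30746                           # W/(m² K)

## per-couple velocity sweep, 12 °C airflow over a 20 °C device
coupleSweep(legMaterial(), legMaterialN(), legGeometry(), air,
            Tlower = celsiusToKelvin(20), Tair = celsiusToKelvin(12),
            velocities = 1:5)
#>   velocity_mps   dT_K      v_oc_V
#> 1            1 -1.739 -0.0007171
#> 2            2 -2.256 -0.0009303
#> 3            3 -2.598 -0.0010715
#> 4            4 -2.857 -0.0011781
#> 5            5 -3.065 -0.0012639
```

The airflow cools the upper face progressively harder as the inlet speed
rises: both |ΔT| and the open-circuit couple voltage grow monotonically,
about −0.72 mV/couple at 1 m/s to −1.26 mV/couple at 5 m/s.

```r
## cough train -> voltage trace -> events -> alarm
fl <- genCoughTrain("severe", count = 3, window = 5, seed = 42)
tr <- simulateResponse(devicePlate(), air, fl, Tupper0 = celsiusToKelvin(20))
(ev <- detectCoughs(tr))
#>   time peak_voltage norm_rise intensity
#> 1 0.57    0.2932401 0.3949361    severe
#> 2 2.84    0.2331194 0.3986678    severe
#> 3 4.91    0.2051781 0.3971276    severe
alarmRule(ev)
#> AlarmState: ACTIVE at t = 4.91 s (3 contributing severe events)
```

Three severe coughs land inside the 5 s window, each converting ~40 % of
the available air–surface temperature contrast, so the alarm fires at the
third event.  See `vignettes/airtherm-methods.Rmd` for the model's
assumptions, the generator design, and the classifier configurations, and
`inst/cli/airtherm.R` for the command-line surface
(`simulate | sweep | synth | detect | run`).

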