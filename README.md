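# lptcmotion

A four-layer computational model of the *Drosophila* optic lobe — retina,
lamina, medulla, lobula complex — for robustly and stably detecting the
motion direction of a translating object under variable figure–ground
contrast and environmental noise, together with the synthetic stimulus
generator and the evaluation metrics needed to benchmark it. It is aimed at
computational neuroscientists and bio-inspired-vision engineers who want a
reproducible, tested reference implementation of an LPTC-based direction
detector.

## The model

For grayscale frames $L(x,y,t)$:

1. **Retina** — luminance change by successive-frame differencing,
   $P = L_t - L_{t-1}$.
2. **Lamina** — half-wave rectification into ON/OFF channels
   ($L_{ON} = \max(P,0)$, $L_{OFF} = \max(-P,0)$); cluster-based spatial
   denoising (each channel is scaled by its normalized 3×3
   neighbourhood-average passing coefficient
   $\mathrm{NPC} = \mathrm{ALC}/(\Delta_c + \max \mathrm{ALC})$, then a
   threshold comparison removes decayed isolated excitation); delayed
   lateral inhibition by the previous step's 3×3 surround.
3. **Medulla** — divisive contrast normalization
   $N = \tanh(S/(\hat S + \psi))$ with $\hat S$ an 11×11 Gaussian surround
   ($\sigma = 5$); centre–surround contrast pathways $C = N - W_1 * N$;
   four-directional T4 correlators on the ON channel, e.g.
   $\mathrm{T4}_R = N(x{+}sd,y)N^D(x,y) - N(x,y)N^D(x{+}sd,y)$.
4. **Lobula complex** — T5 correlators on the OFF channel; convergence on
   the LPTC, $\mathrm{LPTC}_X = [\mathrm{T4}_X - C_{ON}]_+^{\gamma_1} +
   [\mathrm{T5}_X - C_{OFF}]_+^{\gamma_2}$; LPi direction opponency giving
   per-frame vertical/horizontal system responses $VS_t$, $HS_t$, whose
   signs decode up/down and right/left motion.

Reference parameters: $\Delta_c = 0.01$, $\psi = 20$, $\sigma = 5$,
$sd = 4$, $\gamma_1 = \gamma_2 = 0.5$. See the methods vignette
(`vignettes/motion-direction-model.Rmd`) for the full account, including
the stability metrics (per-frame coefficient of variation across contrast
or noise ensembles, its inter-quartile range and sum, and the detection
success rate).

## Worked example

Render the benchmark stimulus (500×250 field, background grey 1, object
grey 150 translating leftward at 2000 px/s, 100 frames at 30 fps), run the
full model, and decode the direction per frame:

```r
library(lptcmotion)

spec <- study_stimulus_spec(gray = 150, direction = "left")
seq  <- render_sequence(spec)
seq
#> frame_sequence: 100 frames of 250 x 500 px at 30 fps

out <- run_model(seq)
head(out, 4)
#>   frame vs        hs decision
#> 1     3  0 -299.0982     left
#> 2     4  0 -299.0982     left
#> 3     5  0 -149.5491     left
#> 4     6  0 -299.0982     left

detection_rate(out$decision, "left")
#> [1] 100
```

The vertical channel is exactly silent for pure horizontal motion, the
horizontal response is negative (leftward) on every evaluated frame —
frames 1–2 are differencing/delay warm-up and are excluded — and the
detection success rate over the 98 evaluated frames is 100%.

Noise robustness and the ablation studies are driven the same way:

```r
# detection under salt-and-pepper corruption of 4% of the pixels
b <- run_pure_benchmark(noise = noise_spec("salt_pepper", spn_ratio = 0.04),
                        seed = 1)
b$dr     # pooled detection rate over 10 object greys x 4 directions

# stability with and without the spatial denoising mechanism
st <- denoise_ablation_study(seed = 1)
st$s_reduction_pct   # % reduction of the summed coefficient of variation
```

A thin command-line wrapper with `stimgen`, `run`, `evaluate` and
`reproduce` subcommands is installed at `inst/cli/lptcmotion`.

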