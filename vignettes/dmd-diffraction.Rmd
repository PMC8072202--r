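---
title: "Simulating coherent diffraction at digital micromirror devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating coherent diffraction at digital micromirror devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdsim)
```

## The physical problem

A digital micromirror device (DMD) is a dense array of square micromirrors,
each of which flips between two steady orientations, $\gamma_-$ and
$\gamma_+$, about its own diagonal hinge axis. Used as a spatial light
modulator with laser illumination — as in structured illumination microscopy
(SIM), where coherent light is needed for pattern contrast — the tilted
mirror facets act as a two-dimensional *blazed grating*: the periodic mirror
lattice produces a comb of diffraction orders, and the facet tilt steers a
single-mirror diffraction envelope across that comb. Unless the envelope
centre coincides with an order (the *blaze* or Littrow-type condition), the
diffracted energy is split asymmetrically and the device is a poor choice
for coherent illumination. `dmdsim` simulates this physics and solves the
design problem it creates: which incidence angles and which wavelength
combinations make a DMD behave like a simple mirror.

## Model and conventions

Directions toward the source ($\vec a$) and toward the observer ($\vec b$)
are unit vectors with positive $z$, parameterized by angle pairs
$(\varphi, \vartheta)$ through
$\vec a = a_z(\tan\varphi, \tan\vartheta, 1)$,
$a_z = (\tan^2\varphi + \tan^2\vartheta + 1)^{-1/2}$. A mirror surface point
with on-mirror coordinates $(s, t) \in [0, w]^2$ on lattice site
$(m_x, m_y)$ sits at
$\vec d = R(\gamma)\,(s, t, 0)^T + m\,(m_x, m_y, 0)^T$, where $m$ is the
pitch, $w \le m$ the mirror edge, and $R(\gamma)$ the rotation about the
diagonal axis $(1, 1, 0)/\sqrt 2$. In the far field (Fraunhofer regime) a
surface point contributes the phase
$\Phi = k\,\vec d \cdot (\vec a + \vec b)$, $k = 2\pi/\lambda$.

With both directions on the reflective side of the device, the $+$ sign is
what makes the model self-consistent: the single-mirror integral then peaks
exactly where $\vec a + \vec b$ is parallel to the tilted mirror normal,
i.e. at the specular reflection $\vec b = 2(\vec a\cdot\hat\nu)\hat\nu -
\vec a$, and the diagonal restriction reproduces the textbook blazed-grating
equation $n\lambda = m'(\sin\alpha + \sin\beta)$ with $\beta = -\alpha +
2\gamma$ at the envelope centre. A sign convention that instead places the
envelope at retro-reflection would contradict both the reflection law and
every blazed-grating result the package reproduces; the test suite pins the
choice through the envelope-centre and displacement checks.

All user-facing angles are degrees (radians internally); lengths are µm in
the field modules and nm for wavelengths in the planner, matching how these
quantities are usually quoted.

## The four approaches

**Ray tracing** (`raytrace_field()`) draws $K$ parallel rays with Gaussian-
distributed transverse offsets, intersects each with the tilted mirror it
hits (exact line–plane intersection; candidate mirrors from the ray's $z=0$
lattice cell and its 8 neighbours, which is exhaustive because the in-plane
footprint shift $w\sin|\gamma| \approx 1.6\,$µm stays below one pitch at
$|\gamma| = 12^\circ$), and coherently sums unit phasors
$e^{ik\vec d_k\cdot(\vec a + \vec b)}$ per output direction. Rays in gaps or
outside the array are discarded. The beam profile enters only through the
sampling density. This is the slowest but least constrained approach — per-
ray wavelength or phase distributions (partial coherence) would be natural
extensions of the same loop, and the interface keeps the per-ray quantities
accessible for that reason, but no coherence model beyond monochromatic
light is implemented.

**Analytic phase shifting** (`analytic_dmd_field()`) assumes constant field
amplitude across each mirror and only the two steady tilt states. The
integral over a single mirror then has a closed form: it separates along the
two rotated in-plane axes into
$w\,e^{iq_ew/2}\,\mathrm{sinc}(q_ew/2)$ factors with
$q_e = k\,(R(\gamma)\hat e)\cdot(\vec a + \vec b)$ — `sinc` here is the
unnormalized $\sin x / x$, a convention stated in the code because the
$\pi$-scaled variant is an easy trap. The closed form is not taken on
faith: the suite checks 200 random configurations against 2-D
Gauss–Legendre quadrature of the raw integrand to better than $10^{-8}$
relative. The full field is the pattern-weighted lattice sum of the two
reference-mirror fields times per-site phase factors; it is evaluated as a
complex quadratic form ($V_x^T W V_y$ per tilt state), so the per-direction
cost is one $n_x \times n_y$ matrix contraction and exactly two
single-mirror evaluations.

**Envelope × grating** (`grating_intensity()`) adds the assumption of
uniform tilt and uniform illumination, upon which the field factorizes into
the single-mirror envelope times a lattice factor that is a product of two
Dirichlet kernels $\sin(N\xi/2)/\sin(\xi/2)$ (with the removable
singularity at each order evaluating to $N$, handled by an explicit
L'Hôpital branch below $|\sin(\xi/2)| < 10^{-9}$). It cannot represent
displayed patterns, but it makes order-level analyses cheap:
`displacement()` measures the great-circle angle between the envelope
centre and the native order with the highest envelope intensity. The
grating factor has equal peak modulus $n_x n_y$ at every order, so the
envelope alone decides which order is "brightest"; orders are enumerated
analytically from the 2-D grating equation rather than by grid search, and
a dense-grid argmax exists in the tests as an independent check. At the
sub-0.1° scales that matter here the great-circle metric is
indistinguishable from Euclidean distance in the angle plane.

**Blaze-condition planner** (`blaze_order_real()`, `solve_blaze_incidence()`
and friends) restricts everything to the device diagonal: mounting the DMD
rotated by 45° confines incidence and diffraction to the plane spanned by
$\vec k = (1,-1,0)/\sqrt 2$ and $z$, where the lattice constant becomes
$m' = m/\sqrt 2$ and angles map through $\alpha = \arctan(\sqrt 2
\tan\varphi)$. Both $\sqrt 2$ factors are pinned by tests: projecting the
3-D anti-diagonal direction onto $\vec k$ reproduces
`diagonal_angle()` exactly, and only $m' = m/\sqrt 2$ reproduces the
$-40.6^\circ/16.6^\circ$ solution pair for order $-4$ at 488 nm with
$\gamma = -12^\circ$ (a halved lattice constant has no solution there at
all). The blaze metric $v = |\sin(n\pi)|$, evaluated at the real-valued
envelope-centre order $n = (m'/\lambda)(\sin\alpha + \sin(-\alpha +
2\gamma))$, vanishes exactly on blaze loci. Solving $n\lambda = 2m'
\sin\gamma\cos(\alpha-\gamma)$ for $\alpha$ is closed-form
($\alpha = \gamma \pm \arccos\frac{n\lambda}{2m'\sin\gamma}$), so there are
no iteration or tolerance questions; both branches are returned and callers
choose, since the two are exchanged under $\alpha \leftrightarrow \beta$.

## Multicolour design

Two wavelengths share one blazed geometry and tilt state when
$n_1\lambda_1 = n_2\lambda_2$; a third colour can reuse the shared
diffraction angle $\beta$ through the opposite tilt state with
$\alpha_3 = -\beta + 2\gamma_+$ and
$\lambda_3 = (m'/n_3)(\sin\alpha_3 + \sin\beta)$.
`plan_three_colours()` chains these steps. For the default device
(7.56 µm pitch, $\pm 12^\circ$) and $\lambda_1 = 488$ nm with orders
$(-4, -3, 4)$ this yields $\lambda_2 = 650.67$ nm at
$\alpha_{1,2} = -40.58^\circ$, $\beta = 16.58^\circ$, and
$\lambda_3 \approx 553.9$ nm at $\alpha_3 = 7.4^\circ$ — a blue/red/yellow
triple compatible with common fluorophores. $\lambda_3$ is sensitive to the
exact tilt angle and to rounding of $\beta$ (quoting $\beta$ at $0.1^\circ$
moves $\lambda_3$ by about 0.015 nm); order selection against a visible
band is exposed as a utility with configurable bounds (default 380–700 nm)
rather than hard-coded, since "visible" is an instrument choice.

```{r}
plan <- plan_three_colours(488, -4, -3, 4)
unlist(plan[c("lambda2_nm", "alpha12_deg", "beta_deg",
              "alpha3_deg", "lambda3_nm")])
```

## Defaults, tunables and degenerate inputs

* **Geometry** — pitch 7.56 µm, mirror edge 7.56 µm (zero gap), tilt
  $\pm 12^\circ$, $50 \times 50$ mirrors. These match a widespread DLP
  device class; the equal pitch/edge reflects the stated mirror size of
  that device, and every value is overridable because real devices have
  small gaps. The 50 × 50 sub-array keeps diffraction orders visibly
  broadened (Fourier broadening) and computations cheap; larger arrays
  sharpen the orders without moving them.
* **Beam** — Gaussian, described by the 1/e² intensity radius (waist). The
  default waist is 5× the array width, centred on the array: amplitude is
  then uniform to ~2% across the mirrors, so comparisons against the
  uniform-illumination approaches are meaningful, while a useful fraction
  of Monte-Carlo rays (~2%) still strikes the array. A much wider beam
  buys negligible extra uniformity but starves the ray tracer: the
  Monte-Carlo noise floor in normalized intensity is $1/H$ for $H$ hitting
  rays.
* **Rays** — default $K = 10^5$. At the default beam this yields a noise
  floor around $5\cdot10^{-4}$ of the main peak, enough for order positions
  and envelope structure; halve the noise by quadrupling $K$.
* **Output grids** — degrees, default $-15^\circ..15^\circ$ at $0.1^\circ$
  (301 × 301). Displacement maps default to the conventional
  $-60^\circ..60^\circ$ at $0.2^\circ$ but any step is accepted; the package
  examples and tests use coarser grids to stay fast.
* **Degenerate cases** — angle conversions refuse $|\varphi| \ge 90^\circ$
  and $z \le 0$ directions; `solve_blaze_incidence()` returns an empty
  frame (with a message) when $|n\lambda| > 2m'|\sin\gamma|$ and merges the
  two branches when the arccosine argument hits $\pm 1$; the envelope
  centre can leave the $z > 0$ hemisphere at extreme incidences, which
  `displacement()` reports as an error and `displacement_map()` records as
  `NA`; `raytrace_field()` errors if no ray hits the device. Removable
  singularities (sinc at 0, Dirichlet kernels at orders) are handled by
  explicit limit branches, switched below thresholds chosen so both
  branches agree to machine precision at the crossover.

## What the tests do and do not show

The synthetic configurations used throughout the suite emulate a coherent,
monochromatic, perfectly collimated Gaussian beam hitting a geometrically
perfect, static mirror array. Passing tests therefore demonstrate the
internal consistency of the four approaches (identical order positions,
exact factorization for uniform tilt, Monte-Carlo convergence to the
analytic map) and the correctness of the closed forms against independent
quadrature/brute-force oracles. They do not certify behaviour on real
devices, which add mirror gaps with exposed substrate, tilt-angle errors of
a few tenths of a degree (to which $\lambda_3$ is notably sensitive),
mirror curvature and array flatness errors, polarization effects, and
partially coherent sources — all outside the model. Shadowing and multiple
reflections between neighbouring mirrors are deliberately ignored
(single-bounce model), which is accurate at small tilt angles but would
degrade at grazing incidence.

## Reproducibility

Every stochastic path is seeded (`sample_rays()` restores the caller's RNG
state), map files carry a JSON sidecar with the fully resolved
configuration including the seed, and the CLI logs that configuration to
stderr on every run.
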