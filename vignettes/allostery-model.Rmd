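---
title: "The allostery model behind sbsmma: assumptions, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The allostery model behind sbsmma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbsmma)
```

## The model

Allostery is the modulation of a protein's activity at one site by a
perturbation — ligand binding or a mutation — at a distant site. The
structure-based statistical mechanical model of allostery (SBSMMA)
quantifies this communication in energy units using nothing but a
coarse-grained harmonic picture of the protein:

1. **Harmonic model.** Each residue is a bead at its C-alpha position;
   every pair of beads closer than a cutoff (default 11 Å) is connected by
   a spring with the observed distance as rest length. The second
   derivative of this potential at its minimum is the anisotropic-network
   Hessian, whose orthonormal eigenvectors $e_\mu$ are the normal modes.
   The six zero-frequency modes are rigid-body translations and rotations
   and carry no internal information.

2. **Allosteric potential.** The elastic work a residue $i$ experiences
   when the structure moves along mode $\mu$ is governed by the stiffness
   it feels from its contact neighbours,
   $\varepsilon_{\mu,i} = \sum_{j \in nb(i)} |e_{\mu,i} - e_{\mu,j}|^2$,
   where $e_{\mu,i}$ is residue $i$'s 3-vector block of the eigenvector.
   The amplitude $\sigma_\mu$ of each mode felt at residue $i$ is a
   zero-mean Gaussian with variance $1/\varepsilon_{\mu,i}$, so the
   allosteric potential $U_i(\sigma) = \tfrac12 \sum_\mu
   \varepsilon_{\mu,i}\sigma_\mu^2$ can be integrated analytically.

3. **Perturbations.** Ligand binding is mimicked by introducing strong
   springs among the residues of the binding site; a stabilizing (UP)
   mutation — a substitution to a bulky residue — multiplies every spring
   incident to the mutated position by $\alpha > 1$; a destabilizing
   (DOWN, Ala/Gly-like) mutation multiplies them by $0 < \alpha < 1$.
   Mutations never create or delete springs; binding may create them
   within a pair cutoff.

4. **Free energy.** Comparing the Gaussian ensembles of the unperturbed
   (0) and perturbed ($P$) networks mode by mode gives the per-residue
   allosteric free energy
   $$\Delta g_i = \tfrac12 k_B T \sum_\mu \ln
     \frac{\varepsilon^{(P)}_{\mu,i}}{\varepsilon^{(0)}_{\mu,i}},$$
   and the allosteric **modulation** is its deviation from the chain mean,
   $\Delta h_i = \Delta g_i - \langle \Delta g \rangle_{chain}$ — the
   background-free effect. A site's modulation is the mean of its member
   residues' $\Delta h$, and the **modulation range**
   $\Delta h^{(m\uparrow)} - \Delta h^{(m\downarrow)}$ summarizes the
   generic allosteric leverage of a sequence position. Scanning every
   position produces the N×N Allosteric Signaling Map (ASM), rows =
   perturbing position, columns = responding residue, always paired with
   the inter-residue distance matrix for interpretation.

Positive $\Delta h_i$ means the perturbation increases the elastic work
residue $i$'s neighbours exert on it (it is pushed towards conformational
change); negative values mean it is comparatively rigidified.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 11 Å | contact distance defining the spring network |
| `base_k` | 1 | uniform spring constant (arbitrary units; see invariance below) |
| `alpha_binding` | 10 | spring scale for binding ("strong interactions") |
| `alpha_up` / `alpha_down` | 2 / 0.1 | incident-spring scale for UP / DOWN mutations |
| `binding_pair_cutoff` | 15 Å | furthest site pair a ligand can bridge |
| `temperature` | 300 K | only converts $k_BT$ units to kcal/mol ($k_BT \approx 0.596$ kcal/mol) |
| `n_modes` | all | number of lowest-frequency internal modes summed |
| `epsilon_floor` | 1e-12 | relative $\varepsilon$ floor (below) |
| `rigid_tol` | 1e-12 | relative eigenvalue threshold for rigid modes (below) |

The perturbation magnitudes deserve a comment: the method's structure —
which residues respond, the sign pattern, all symmetry and invariance
properties — does not depend on the exact $\alpha$ values; they set the
overall magnitude of the reported energies. The defaults encode "binding
is a strong, site-wide stiffening; a point mutation is a moderate, local
one". All are configurable per call and through the CLI.

## What the model is provably insensitive to

These are consequences of the equations, and the test suite checks each:

* **Null perturbation.** Identical ensembles give $\ln 1 = 0$: $\Delta g
  \equiv 0$ exactly.
* **Uniform stiffness.** Scaling every spring by $\alpha$ scales
  eigenvalues but not eigenvectors, and $\varepsilon$ depends only on
  eigenvectors, so $\Delta g \equiv 0$. Hence `base_k` is a pure unit
  choice.
* **Rigid motions.** Rotating/translating the input coordinates rotates
  the eigenvectors correspondingly and leaves every $\varepsilon$, hence
  every energy, unchanged.
* **Symmetry.** On an exactly two-fold-symmetric dimer,
  symmetry-equivalent perturbations give $\Delta h$ profiles that map onto
  each other under the chain swap, and the full ASM commutes with the
  swap permutation.
* **Range identity.** The modulation-range map equals UP − DOWN
  elementwise by construction; the code computes it that way and the
  tests verify the scan output satisfies it to machine precision.

In addition, the per-residue $\Delta g$ is cross-checked on small bead
systems against an independent oracle that evaluates each mode's Gaussian
normalization integral $\int \exp(-\tfrac12\varepsilon\sigma^2)\,d\sigma$
by numerical quadrature and takes log-ratios, rather than using the
closed form.

## Numerical choices

**Mode pairing.** The unperturbed and perturbed ensembles are paired by
ascending-eigenvalue rank over internal modes, the only generic
well-defined correspondence; both states retain the same count.

**Neighbour topology for $\varepsilon$.** By default both states use the
*unperturbed* contact topology, so binding-created springs influence the
result only through the modes and the ratio compares like with like;
`topology = "respective"` switches to each state's own neighbour set.

**The $\varepsilon$ floor.** A residue whose neighbourhood barely moves in
some mode can have $\varepsilon$ near machine zero, making the
log-ratio blow up from roundoff alone. Modes whose $\varepsilon$ falls
below `epsilon_floor` relative to that residue's largest $\varepsilon$ —
in either state — are skipped for that residue, symmetrically, and the
count is recorded in the fit (`skipped_modes`).

**Rigid-mode detection.** Modes with eigenvalue below `rigid_tol` times
the largest eigenvalue are classified rigid. Dense symmetric
eigendecomposition leaves the six true zeros at about $10^{-15}$ relative,
while the softest genuine internal modes of marginal geometries
(near-collinear chains) can drop to $10^{-10}$ relative; `1e-12` sits
between the two populations with orders of magnitude to spare on each
side. More than six rigid modes is diagnosed as a disconnected or
geometrically degenerate structure and reported with the connected
components; the two-bead system, whose only internal motion is the
stretch, is the documented five-rigid-mode special case.

**Degenerate eigenvalues.** Within a degenerate eigenvalue subspace the
individual eigenvectors are solver-dependent, and $\Delta g$ can vary with
the basis choice. Perfectly symmetric or ideal-geometry inputs can have
such spectra; the fixture generator therefore supports a small seeded
jitter, and the test suite compares only basis-invariant quantities or
uses fixtures with simple spectra. For real structures, whose coordinates
are never exactly symmetric, this is rarely a concern.

**Chain breaks.** Residues missing from the crystal are simply absent
from the network; no pseudo-bonds are added across sequence gaps, so a
gap wide enough to disconnect the structure is reported as such rather
than silently bridged.

## The synthetic structures

`generate_fixture()` produces deterministic C-alpha-only poly-alanine
toys: a linear bead chain, an ideal alpha-helix (1.5 Å rise, 100° twist,
2.3 Å radius), a cubic-lattice cluster, a two-domain dumbbell, and an
exactly two-fold-symmetric dimer. Three of their design details matter
and were chosen once, for rigidity of the spring network rather than for
any result:

* the cubic cluster fills the lattice diagonal-shell-first, so even four
  beads form a tetrahedron instead of a degenerate planar square;
* the dumbbell's linker coils off the inter-domain axis at compressed
  spacing — a straight on-axis linker leaves an exactly free
  inter-domain torsion, and a domain anchored to fewer than three
  non-collinear linker beads can still pivot;
* the dimer applies its jitter to chain A *before* mirroring, so the
  two-fold symmetry is exact at any jitter amplitude — which is what the
  symmetry tests need — while the jitter still removes the ideal helix's
  near-degenerate spectrum.

A perfectly straight chain is a degenerate input for an anisotropic
network (transverse displacements cost nothing at first order), and a
3.8 Å-spaced chain under an 11 Å cutoff has fewer than $3N-6$ springs;
chain-based analytic tests therefore use 3.0 Å spacing plus jitter, which
restores $i,i{+}3$ contacts and generic rigidity.

These toys exercise every code path — multi-chain bookkeeping, symmetry,
domain architecture — but they are not proteins: they have no side
chains, no realistic packing density or contact-order distribution, and
their spectra are far simpler than a real fold's. Passing tests on them
demonstrates the correctness of the machinery and the model's exact
properties, not predictive accuracy on real allosteric systems.

## Problem sizes and cost

A fit costs two dense eigendecompositions of $3N \times 3N$ matrices; a
full ASM scan costs $N{+}1$. The test suite works at $N \le 30$ and the
demonstration scan at $N = 100$ (a few seconds on one CPU). Dense
decomposition remains practical to roughly $N \approx 1000$ at a desk;
beyond that a sparse or truncated eigensolver would be the natural
extension, which this package deliberately does not include.

## Known limitations

* The absolute energy scale inherits the arbitrariness of the
  perturbation magnitudes; comparisons are meaningful within a run
  (between residues, sites or positions), and signs and rankings are the
  robust outputs.
* All non-rigid modes are summed by default; whether a low-frequency
  subset would be preferable is exposed as `n_modes` rather than decided.
* The unweighted $\varepsilon$ formula is used as printed; weighting
  neighbour terms by spring constants would be a model variant, not an
  option here.
* Only the first MODEL and the first altLoc of a PDB file are read;
  HETATM records (ligands, waters) never enter the network — binding is
  always represented through the site perturbation, not by adding ligand
  beads.
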