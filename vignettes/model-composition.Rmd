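---
title: "Methods: model fusion, annotation matching, and kinetic verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model fusion, annotation matching, and kinetic verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlfuse)
```

## The fusion model and its assumptions

`sbmlfuse` composes two SBML models by *fusion*: the output is one flat
SBML document with shared elements de-duplicated and per-source
provenance discarded (the operation is not reversible; the id maps
returned by `compose()` are the only record of origin). The procedure
assumes the two inputs share an SBML level and version — element
structure is not comparable across levels, so a mismatch is an error by
default (`fuse_config(level_mismatch = "warn")` downgrades it to a
recorded warning).

Identity between elements is decided by two kinds of evidence:

1. **MIRIAM annotations.** RDF blocks inside an element's `annotation`
   are reduced to normalized keys `(qualifier, collection, identifier)`.
   Both the legacy URN syntax and identifiers.org URLs occur in curated
   files, so both are normalized to the same key (percent-decoding the
   identifier, lowercasing and de-aliasing the collection, e.g.
   `obo.chebi` → `chebi`). Only the `is` qualifier certifies identity by
   default: `isVersionOf` asserts a broader relationship, and treating
   it as identity can merge distinct variants of an entity. A lenient
   mode (`match_mode = "lenient"`) accepts `isVersionOf`/`hasVersion`
   for corpora where curators used them loosely. Two *unannotated*
   elements never match by annotation — absence of evidence is not
   evidence of identity — so annotation matching degrades silently to
   name matching when annotations are missing.
2. **Exact effective names.** Comparison uses the `name` attribute when
   present and the `id` otherwise. The fallback is load-bearing:
   Test-Suite-style models carry only ids, and without it nothing would
   ever match on such files. Comparison is exact and case-sensitive; we
   deliberately do no fuzzy matching (a known limitation, see below).

The per-class rules are: compartments match on name-or-annotation;
species on annotation, or name plus corresponding compartments (the
model-2 compartment mapped through the compartment pairing first);
reactions on (annotation or name) *and* equal reactant and product
species multisets, with stoichiometry excluded from the test. The
reaction connective is a genuine design decision: the underlying method
description enumerates annotation, name, reactant and product
conditions together, but requiring a shared annotation would make
matches impossible on annotation-free corpora, and the reference
worked example (equal names, different lists, no merge) is consistent
with the `(annotation ∨ name) ∧ reactants ∧ products` reading we
implement.

Matching runs compartments → species → reactions because each rule
consumes the previous pairing. The automatic matcher is greedy and
deterministic: model-1 document order, first unclaimed model-2
candidate. When the eligibility graph is a partial bijection (the
common case — names are unique within a model) greedy attains the
brute-force maximum matching; on ambiguous graphs its output is a
subset of some maximum matching, with the document-order tie-break
making results reproducible. Manual pairs always win and may connect
elements the automatic rules would not.

**The pivot rule.** On every merged pair, model 1's attributes are kept
wholesale. A conflict (both sides carry a value, values differ) is never
resolved silently: it produces an `attribute-conflict` warning whose
`chosen` field always equals model 1's value. Absence is not a conflict.
Model-2 global parameters are never merged — parameter semantics depend
on every kinetic law that references them, and merging parameters that
merely share an id (`k1` is near-universal) would corrupt rate laws; the
same reasoning keeps unit definitions, function definitions, rules and
events un-merged, carried verbatim with collision renaming.

**Renaming.** Surviving model-2 elements keep their ids unless they
collide (or `prefix_all` is set), in which case they get the
`<model2-id>_` prefix, with `_2`, `_3`, ... suffixes should the
prefixed id itself be taken. Renaming only on collision is a decision:
the reference behavior is only documented for colliding cases, and
gratuitous renames would make composed models needlessly diff-hostile.
After renaming, every reference in the carried fragments is rewritten
through the id map; kinetic-law rewriting skips identifiers shadowed by
the law's local parameters, and an identifier that ends up with neither
a mapping nor a declaration in the composed model is a hard consistency
error rather than a silent emission.

## Simulation

`build_ode_system()` turns the reaction network into
`d[S]/dt = Σ_r ν_{S,r} v_r / V_S` for ordinary species (state held as
concentration), with no compartment division for species declaring
`hasOnlySubstanceUnits` (state held as amount). Boundary and constant
species keep zero derivative while still driving rates. Assignment
rules are evaluated before every derivative call; events, rate rules,
algebraic rules, initial assignments and delay terms are rejected with
a named "unsupported for simulation" error — composition still carries
them through untouched, so a composed model containing them remains a
valid document even though this engine will not integrate it.

The integrator is an adaptive Dormand–Prince 5(4) (compiled, with
standard error-per-step control `err ≤ atol + rtol·|y|`, step-factor
clamps 0.2–5 and safety 0.9). Defaults mirror the reference engine's:
`abs_tol = 1e-16`, `rel_tol = 1e-6`; `n_points = 100` output points
(a display choice left to the user in the original interface). Output
is sampled by clamping steps onto the requested grid — no dense-output
interpolation, so reported states are genuine solution points.
Tolerances, time window, parameter and (strictly positive) initial
overrides, and species/flux selections are the knobs exposed by
`simulation_settings()`. Fluxes are the kinetic laws evaluated along
the trajectory.

The test oracle is deliberately a different code path end to end:
`reference_trajectory()` builds mass-action rate arrays *directly from
the parsed reaction scheme* — never touching SBML serialization, MathML
or the adaptive solver — and integrates with a fixed-step classical RK4
at `h = 1e-4 ×` span. Agreement between the two routes therefore
validates the whole pipeline (generator → writer → parser → math
compiler → adaptive solver) rather than the integrator alone. Linear
conservation laws (left null space of the stoichiometry matrix) are
preserved exactly by any Runge–Kutta step, so conserved-moiety drift in
the enzyme fixture tests arithmetic and assembly, not integration
accuracy — which is why the `1e-6` drift bound is safe at default
tolerances.

## The synthetic fixtures: what they do and do not establish

`scheme_to_model()` emulates the small kinetics-test models the
composition method was originally exercised on: one compartment of size
1, all species at initial concentration 1, sequential `reaction1..n` /
`k1..n` ids, pure mass-action laws `k·V·Π[R]^s` (reversible laws as
forward-minus-reverse with two constants), and `X0`/`X1` treated as
boundary species. Defaults (size 1, initial 1) are choices made once
for closed-form checkability; rate constants default to 1, or are drawn
uniformly from [0.1, 10] under a seed — a range keeping the toy systems
well-scaled and non-stiff. The worked-example pair fixes
`case00015` = `S1 -> S3, S3 -> S1` with k = (1, 0.5) and
`case00020` = `S1 -> S2, S2 -> S4` with k = (0.8, 0.6): the constants
are unpublished, so these are the package's own documented values; the
`case00020` scheme is constructed so that every documented structural
fact of the reference composition holds simultaneously (species union
S1–S4 with only S1 shared, equal reaction names with different lists,
colliding `k1`/`k2`), which a literal two-step truncation of the group-11
chain cannot satisfy.

A green fixture suite establishes that the merge rules, renaming,
reference rewriting and the ODE engine behave correctly on well-formed,
annotation-light, mass-action models. It does *not* establish
robustness against the messiness of real curated files — inconsistent
naming conventions, rich annotation sets with conflicting qualifiers,
exotic kinetic laws, or models relying on events and rules — nor does
the 100-pair robustness run reproduce any corpus-level success
statistic, since the original corpus is external.

## Numerical choices

* Numbers serialize in the shortest decimal form that survives an
  `as.numeric` round-trip; scientific notation is accepted on input.
* Similarity percentages use the Dice coefficient
  `100·2|M|/(|A|+|B|)` (symmetric, bounded, 0 for two empty classes);
  the formula was unspecified upstream, and `|M|/min(|A|,|B|)` is
  available as a config option for users who want containment rather
  than overlap.
* Carried opaque fragments are canonicalized (whitespace-only text
  nodes normalized, the redundant inherited core namespace declaration
  stripped) so that parse → write → parse is a byte-stable fixed point.
* The composed document is stamped with model 1's level/version (the
  upstream behavior is undocumented; pivoting on model 1 is consistent
  with every other rule).
* Division by zero and unresolved identifiers in math evaluation are
  errors carrying the expression path; piecewise takes the first true
  branch and falls back to `NaN` without an `otherwise`.

## Known limitations

No approximate name matching; no SBO-hierarchy reasoning (sboTerm
conflicts are warned, never matched on); no merging of units,
parameters, or function definitions; no SBML Level 1 and no
hierarchical-composition package semantics; events/delays/rate rules
carried but not simulated; substance and size units are trusted, not
converted. Modifier lists are excluded from the reaction equality test
(only reactants and products are specified upstream) and are unioned on
merge.
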