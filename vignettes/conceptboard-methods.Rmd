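---
title: "Methods: neural blackboard binding and entropy-driven chunking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural blackboard binding and entropy-driven chunking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptboard)
```

This vignette is the package's own account of its models: the dynamical
substrate, the blackboard machinery, the control scripts, the layered
chunking memory, the conceptual-space geometry, and the numerical choices
behind each. Nothing here states an empirical result the tests do not
themselves compute.

## 1. Population dynamics

Every element of the blackboard is a neural population with activity
$A \in [0, 1]$ obeying the Wilson-Cowan rate equation

$$\tau \dot A = -(A - A_0) + (1 - A)\, F(u), \qquad
  F(u) = \sigma\!\big(g (u - \theta)\big) - \sigma(-g\theta),$$

where $u$ collects recurrent drive $w_{\mathrm{self}} A$, weighted link
inputs, a tonic bias, and external stimulation; $\sigma$ is the logistic
function. The subtracted constant makes $F(0) = 0$, so the rest state
$A = A_0$ is exactly a fixed point — the classical rectified form. The
saturating factor $(1-A)$ caps the activity a purely feed-forward
population can sustain at $F_{\max}/(1+F_{\max}) \approx 0.47$ under the
default parameters.

**Defaults and why.** $\tau = 10$ ms, $g = 4$, $\theta = 0.5$, baseline
$0$, integration step $dt = 1$ ms, all overridable per population. Only
qualitative activity profiles are claimed for the architecture, so the
canonical parameterization is used rather than anything fitted.

**Bistability.** Populations that must hold state (working-memory nodes,
in-situ concept assemblies, recruited main assemblies) use
$w_{\mathrm{self}} = 2$. Fixed-point analysis of
$-A + (1-A)F(2A) = 0$ under the default sigmoid gives a stable rest
state at $0$, an unstable knee near $0.07$, and a stable reverberating
state near $0.41$; the dynamics tests verify both attractors by
simulation from the two basins. A self-weight of $1$ admits no high
fixed point under these parameters, which is why $2$ is the package
default.

**Integration.** Explicit Euler with clamping to $[0,1]$. At
$dt/\tau = 0.1$ the scheme is stable and first-order accurate; the
step-halving test pins a sup-norm tolerance of $10^{-3}$ on a
feed-forward chain at $dt = 0.1$ ms and verifies that the error of the
recurrent bistable circuit halves with $dt$. Stiff solvers buy nothing
at these time constants.

## 2. The sentence blackboard

Words are *in-situ* concept assemblies — one population per word, never
copied, bound into structures only temporarily. Structure assemblies
come in kinds `S, N, V, Aux, Adj, Adv, Num, PP` with role sub-assemblies
`n, v, t, va, na, ad, nm, pv, pn`; a main and each of its subs are
connected by a *pair* of gating circuits (one per direction), since a
conditional connection must carry activation both ways.

A gating circuit is three populations: relay $X$ (source $\to X \to$
target, weights $2.5$), a tonically active inhibitor $i$ (bias $1$,
blocking $X$ with weight $-4$), and a disinhibitor $di$ that silences
$i$ (weight $-4$). Main-sub circuits are disinhibited by control
(external drive on $di$); binding circuits are disinhibited by WM.

A *connection node* binds two specific sub-assemblies: one WM population
(self-weight 2), an entry gating circuit whose relay feeds the WM
(weight 1.2) and whose disinhibitor is driven by the partner assembly —
so the WM ignites only under co-activity — plus two directional
circuits gated by the WM. That is 10 populations per node ($3 \times 3$
circuits + 1 WM), 7 per main-sub role (sub + two circuits), and 1 per
concept or main population; `expectedPopulationCount()` is the closed
form and the construction is audited against it.

**Numerical choices.**

* *Ignition threshold.* Because sustained feed-forward activity caps
  near $0.47$, the co-activity threshold for `bindIfCoactive()` defaults
  to $0.35$ — below the steady driven level ($\approx 0.42$), above
  transients. In full dynamical runs ignition is emergent through the
  entry circuits and needs no threshold; the integration time of the
  entry circuit (tens of ms) provides the dwell requirement, so the
  discrete operation checks instantaneous co-activity only.
* *Word-flow AND-gates.* The directional circuits of word-main nodes
  use a steeper, higher-threshold disinhibitor ($g = 10$,
  $\theta = 0.8$) receiving the node's WM (weight 1) plus a global
  word-flow control drive (0.5). Each input alone leaves the gate fully
  blocked. This matters twice: during parsing a re-presented word (the
  second *cat*) must not re-excite its already-bound assembly, and
  because $F$ has no hard threshold, a partially open gate would leak
  into bistable populations and eventually ignite them spuriously.
  Retrieval opens the word-flow drive; parsing leaves it closed.
* *Quenching.* The paper-level observation that activity falls after
  binding is realized by the control script withdrawing support from
  consumed assemblies: a strong inhibitory control pulse (amplitude
  $-3$ for the consolidation phase) pushes them below the bistability
  knee. Stimulus schedules for *words* are validated as non-negative;
  control projections may be inhibitory.

**Pools and recruitment.** Pool sizes follow the token inventory of the
sentence (a repeated word re-uses its single concept assembly but needs
a structure assembly per occurrence). Recruitment takes the
lowest-index unrecruited assembly of a kind — deterministic and
testable — and exhausting a pool is an explicit error, since silent
reuse semantics are not defined. WM bindings do not decay on their own;
`resetBindings()` is the explicit clear.

## 3. Control scripts and the reservoir

Parsing is choreographed: a trained readout maps category sequences to
command scripts over the vocabulary `recruit(kind)`, `open(kind, role)`,
`close(kind, role)`, `quench(kind, which)`. The reservoir is the
chaining mechanism that presents category n-grams (node $k$ can only
fire after node $k-1$, so permuted token orders fall off the trained
chain and raise a parse error); readout training is exact association —
contradictory examples are an error, unseen sequences are rejected, and
generalization comes from categories, not from gradient learning.
Coverage is deliberately exactly the three fixture constructions and
the wh-queries over them.

Each word interval (default 200 ms, a value in the range of spoken word
rates; the paper-level figures show presentation bars without numbers)
divides into presentation (70 ms: word pulse plus recruitment pulses),
binding (80 ms: role gates open, WM ignition through entry circuits),
and consolidation (50 ms: gates close, consumed assemblies quenched).
Bindings happen at the word that completes them; a word that cannot yet
bind backwards (the sentence-initial noun, a numerator whose noun is
still to come) keeps its support, and its consolidation lands one
interval later. This is what produces the characteristic total-activity
profile: a rise within 50 ms of every onset, and a post-peak decline in
every interval except those two.

*Operationalizing the profile check:* an interval "declines" if total
activity falls below its running peak, after the peak, by more than 0.5
— one population's worth of sustained activity — so that integration
transients (observed an order of magnitude smaller) do not count as
declines. The check and the margin live in the acceptance test.

**Question answering.** A wh-question is generalized to categories
(`where localizer noun`), and the cued noun's role tag (Agent for `n`,
Theme for `t`, Location for `pn`; first match in that fixed priority
order when a word holds several bindings) is read off the bound
structure — this is the blackboard feedback input to the reservoir, and
it changes when the same noun is rebound, with no change to the token
stream. Retrieval opens the trained role path's gates plus word flow,
pulses the cue, and reports the words whose assemblies were reached
*through the final role of the path*: endpoint assemblies carry an
active final-role sub but not the path's penultimate role, which
excludes way-stations. The probe snapshots and restores network state,
so asking is non-destructive.

## 4. The layered chunking memory

Per viewpoint and per level the memory holds a growing alphabet, the
symbol sequence, a first-order transition matrix, chunk extents, and
up/down link counts to adjacent levels. Prediction is row normalization
with add-one smoothing over the current alphabet, so entropies exist
for unseen contexts (early predictions are simply inaccurate, as they
should be). A mixture across viewpoints weights distributions by
$2^{-H}$, renormalized — sharper predictions weigh more — and is defined
over a common alphabet.

**Boundary decision, exactly.** When symbol $s_t$ arrives: (1) the
alphabet is extended with $s_t$ if new; (2) from the counts *before*
the new transition is added,
$\Delta H = H(D(\cdot \mid s_t)) - H(D(\cdot \mid s_{t-1}))$; (3) the
transition $(s_{t-1}, s_t)$ is counted. Among all level-0 generators
with $\Delta H > 0$, the single largest wins workspace access and its
chunk closes *including* $s_t$ — the boundary sits before the
still-unseen next symbol, where the successor distribution spiked. Two
details deserve their reasons:

* *Pre-update counts.* With post-update counts, the just-incremented
  row is systematically sharper than the next context's row, which
  injects a spurious positive $\Delta H$ at every within-word step. With
  pre-update counts, two contexts inside the same word have identical
  count profiles and $\Delta H$ is exactly zero there, so on a stream
  with deterministic within-word transitions the boundaries land
  exactly at word ends (the segmentation tests and the replay oracle
  check this).
* *Chunk closes including the new symbol.* The entropy spike is in the
  forward prediction *from* $s_t$; cutting before $s_t$ would
  systematically clip the last symbol off every word.

Ties between generators break by viewpoint registration order. Losing
generators' candidate boundaries are kept for the forgetting period
(default 20 events — the underlying duration is an open research
variable, so it is config-exposed) and then discarded. One global
winner is taken per input event among the level-0 generators; the
boundary test then cascades up the levels inside the winner's
promotion, because a higher-level symbol only exists once the lower
chunk has closed — a literal all-levels competition within one event
would be acausal.

**Promotion.** A closed chunk is labelled (same subtended sequence,
same label), the label is appended one level up, the upper transition
matrix is updated, and the down/up link matrices between the levels are
incremented — a higher symbol links down to every symbol in its chunk,
each lower symbol links up to every label whose chunk contains it. The
recursion stops at `maxLevels` (default 3) with a logged notice.

**Mean code length.** The memory's efficiency objective is the average,
over every stored symbol at every level, of its information content
under the current model at its position. A level's first symbol is
scored against the alphabet plus one unit of escape mass (the model had
never predicted yet), which keeps even a single-symbol memory at a
positive, finite value. The i.i.d.-uniform-over-4 law (convergence to
2 bits over $10^4$ symbols) is measured with `maxLevels = 1`, i.e. on
the raw stream: that is the regime in which the law is a statement
about the code, not about chunk labels stacked above it.

**Consolidation** is greedy local search over label merges: a merge
rewrites history (sequence, chunks, transition and link matrices, with
collisions cascading upward) and is kept only if the mean code length
strictly decreases; the search stops at a local minimum, so the code
length never increases across a call. Because the objective counts only
sequential predictability, chunk labels whose order carries no
information (e.g. words drawn i.i.d.) can legitimately collapse to one
category; corpora with sequential structure retain their distinctions.
Single-chunk relabelling is subsumed by merges for symbolic memories.

## 5. Conceptual spaces

Symbols are seed points in a Euclidean space (optionally per-dimension
weighted). Classification is by half-spaces: for each seed pair the
separating hyperplane is perpendicular to the connecting segment,
offset from the midpoint toward the less likely symbol by
$\alpha \frac{p(s) - p(s')}{p(s) + p(s')} \cdot \frac{\lVert s-s'\rVert}{2}$
— this is the package's concretization of boundary movement "in
proportion to relative likelihood"; $\alpha$ defaults to $0.5$ and,
with the entropy-scaling flag, is multiplied by $1 - H(D)/\log_2 |A|$
so that diffuse expectations move boundaries less. A gap $g$ shrinks
every region by $g/2$ per side; points in the gap zone classify as
`GAP` and become new seeds. With $g = 0, \alpha = 0$ this is exactly
nearest-seed Voronoi classification (tested against the brute-force
oracle in 2 and 8 dimensions); boundary ties resolve to the lowest
symbol index; modulation is transient — seeds never move. The
discriminability tolerance of `addSeed()` is $10^{-6}$. A space with a
single seed has no pair boundary, so its gap parameter doubles as the
lone seed's catchment radius until a second seed exists — without this,
continuous viewpoints could never grow a second symbol.

**Abstraction.** A trajectory (points with durations) is resampled
piecewise-constantly to 32 samples and transformed per dimension with a
discrete cosine basis; the magnitudes of the first $k = 8$ coefficients
concatenate into the higher-level point. Any fixed orthogonal spectral
basis satisfies the design goal; the DCT is real-valued and makes the
constant trajectory map to (DC, 0, ..., 0). Resampling in normalized
time makes the result exactly invariant to uniform dilation — the same
word is recognized however long the vowel takes. Down-prediction uses
stored chunk extents, not spectral inversion, which the transform does
not define.

## 6. The bridge

Chunk trees do not correspond to syntactic parses, so the compiler maps
chunk *categories* to blackboard kinds through an explicit, per-corpus
role map: token kinds, containment roles (a sentence chunk binds its
first noun child via `n`, first verb via `v`), argument rules (a noun
fills the slot of its nearest preceding verb `t` or preposition `pn`,
nearest governor winning), and modifier rules (numerator/adjective/
auxiliary attach forward, adverbs forward to adjectives, prepositions
backward to verbs). One assembly is recruited per chunk — conservation
is tested — and bindings are ignited directly in the connection nodes'
WM populations (the compiler is post hoc; it does not co-simulate with
the chunker). Round-trip isomorphism between the compiled and the
dynamically parsed structure, label-preserving under VF2 with vertex
and edge colors, is the integration check for all three fixture
sentences.

## 7. The synthetic corpora

`genArtificialLanguage()` emulates the classic segmentation setting:
words with deterministic internal transitions, concatenated i.i.d.
(default three trisyllabic words over nine distinct syllables, uniform
selection, 900 tokens), with ground-truth boundaries emitted alongside.
What it does *not* emulate: coarticulation, noise on symbols, skewed
word frequencies, or any semantic correlation between words — passing
the segmentation tests therefore shows the boundary-entropy machinery
is correct, not that it segments natural speech. `genJLM()` provides an
11-phoneme multi-viewpoint stream whose pitch and amplitude contours
are synthetic smooth curves: their only job is to exercise continuous
viewpoint symbolization through conceptual spaces, and they model
nothing about real prosody.

## 8. Problem sizes and limitations

The test suite simulates the nine-word sentence blackboard (555
populations, 1.8 s of simulated time at 1 ms steps), learns 900-token
corpora, and measures the code-length law at $10^4$ symbols — sizes
chosen so the full suite runs in well under a minute while every
mechanism is exercised at its intended scale.

Known limitations: control coverage is exactly the fixture
constructions (broad-coverage parsing is a non-goal); the word interval,
pulse amplitude, and phase timings are package choices because the
underlying presentation parameters are not published; ambiguity
competition between rival parses is not modelled; the chunker is
strictly first-order per level (long-range context enters only through
the layer hierarchy); and conceptual-space geometry is not learned from
corpora — spaces are supplied, not inferred.
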