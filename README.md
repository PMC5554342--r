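# conceptboard

Two cognitive architectures in one package, plus the bridge between them:

* a **neural blackboard** for compositional sentence representation:
  concepts are *in-situ* neural assemblies that are never copied; a
  sentence is a temporary *connection path* built from structure
  assemblies (N, V, S, Aux, Adj, Adv, Num, PP), gating circuits and
  bistable working-memory (WM) populations, all simulated with
  Wilson-Cowan rate dynamics;
* an **information-dynamics sequence learner**: an incremental, layered
  memory over symbol streams that segments its input by boundary entropy
  (a chunk closes where the predictive distribution's entropy rises),
  labels chunks, and recursively chunks the label sequence, grounding
  symbols in geometric conceptual spaces tessellated Voronoi-style with
  gaps and expectation-modulated boundaries;
* a **compiler** that maps a chunk hierarchy onto blackboard bindings, so
  that structures learned from data can be realized in neural dynamics.

## The models in brief

Every blackboard element is a population obeying

```
tau dA/dt = -(A - baseline) + (1 - A) F(w_self A + sum(inputs))
F(x) = logistic(g (x - theta)) - logistic(-g theta)
```

with defaults `tau = 10 ms`, `g = 4`, `theta = 0.5`. Populations with
`w_self = 2` are bistable: a brief suprathreshold pulse leaves them
reverberating, which is how a WM population holds a binding. A gating
circuit (relay `X`, tonically active inhibitor `i`, disinhibitor `di`)
blocks flow until `di` silences `i`; a connection node binds two
sub-assemblies with one WM population, an entry circuit that ignites the
WM under co-activity, and two WM-disinhibited directional circuits.

The sequence learner keeps, per viewpoint (feature stream) and per level,
an alphabet, a first-order transition matrix with add-one smoothing, and
the predictive distribution `D(. | s)` for each context `s`. On each new
symbol the change `dH = H(D(. | s_t)) - H(D(. | s_t-1))` is computed; the
generator with the largest positive `dH` wins global-workspace access and
closes its chunk. Consolidation greedily merges chunk labels whenever the
merge reduces the mean stored code length (bits per symbol).

## Worked example

```r
library(conceptboard)

fx <- sentenceFixture("cat-is-on-mat")
bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
res <- parseSentence(fx$tokens, fx$lexicon, bb)
res$graph
#> BindingGraph: 9 vertices, 8 bindings
#>   cat -[word]- N1
#>   is -[word]- V1
#>   on -[word]- PP1
#>   mat -[word]- N2
#>   S1 -[n]- N1
#>   S1 -[v]- V1
#>   V1 -[pv]- PP1
#>   PP1 -[pn]- N2

answerQuestion(c("where", "is", "cat"), fx$lexicon, bb)
#> [1] "mat"
```

The graph is the sentence's connection path: the word *cat* is bound to
noun assembly `N1`, which fills the sentence assembly's subject role `n`;
*on* heads a preposition assembly linking the verb (`pv`) to *mat*'s
assembly (`pn`). The question is answered content-addressably: the cue
*cat* re-activates its own assembly, the trained role path
`n -> v -> pv -> pn` is opened, and activation arriving at the far end
re-ignites the concept *mat*.

On the learning side:

```r
al <- genArtificialLanguage(seed = 7)        # 3 trisyllabic words, 900 tokens
mem <- IdyotMemory(chunkerConfig(maxLevels = 2))
registerViewpoint(mem, "syll")
for (ev in al$events) observeEvent(mem, ev)
tail(chunkExtents(mem, "syll", 0)$end)       # boundaries fall at word ends
#> [1] 885 888 891 894 897 900
```

A command-line front end for the same operations is in
`inst/scripts/conceptboard` (`simulate`, `parse`, `ask`, `learn`,
`genlang`, `compile`).

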