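#' @import methods
NULL

#' Rate-coded neural population network
#'
#' A `RateNetwork` holds a set of neural populations obeying Wilson-Cowan
#' rate dynamics together with the weighted links between them.  Populations
#' are characterised by a time constant `tau` (ms), a sigmoid `gain` and
#' `threshold`, a resting `baseline`, a tonic `bias` input and a recurrent
#' `selfWeight`.  Activity is dimensionless and clamped to `[0, 1]`.
#'
#' State lives in an environment slot so that a network can be grown and
#' stepped in place; use the accessors rather than touching the slot.
#'
#' @slot env internal state environment.
#' @export
setClass("RateNetwork", representation(env = "environment"))

#' Sampled activity of a network run
#'
#' Activity of every population sampled on a regular time grid, produced by
#' [runNetwork()].  The `total` series is the point-wise sum of all
#' population activities.
#'
#' @slot time numeric vector of sample times (ms).
#' @slot activity matrix, one column per population, one row per sample.
#' @export
setClass("ActivityTrace",
         representation(time = "numeric", activity = "matrix"))

#' Sentence neural blackboard
#'
#' A blackboard is a structured pool of binding machinery built on top of a
#' [RateNetwork-class]: in-situ concept assemblies (one per word), pools of
#' structure assemblies per syntactic kind (each a main assembly plus
#' role-labelled sub-assemblies), gating circuits between mains and subs,
#' and connection matrices of working-memory (WM) gated connection nodes
#' that implement temporary bindings.
#'
#' @slot env internal state environment (network, inventories, gate state).
#' @export
setClass("Blackboard", representation(env = "environment"))

#' Labelled binding graph
#'
#' The connection-path structure held on a blackboard (or compiled from a
#' chunk hierarchy): vertices are words and structure assemblies, edges are
#' role-labelled bindings.
#'
#' @slot vertices data.frame with columns `id`, `type` (`"word"` or
#'   `"assembly"`) and `label` (the word itself, or the assembly kind).
#' @slot edges data.frame with columns `a`, `role`, `b`.
#' @export
setClass("BindingGraph",
         representation(vertices = "data.frame", edges = "data.frame"))

#' Sequence-node reservoir with a trained readout
#'
#' Control machinery that turns category sequences (plus blackboard
#' feedback) into gate-opening command scripts.  Sequence nodes form a
#' chain, so the node for position k can only become active after the node
#' for position k - 1; the readout is an exact association from presented
#' category n-grams to command scripts.
#'
#' @slot env internal state (chain position, readout maps).
#' @export
setClass("Reservoir", representation(env = "environment"))

#' Layered entropy-chunking sequence memory
#'
#' Incrementally learned hierarchical memory over one or more viewpoints
#' (named feature streams).  Each viewpoint carries a stack of levels, each
#' with its own growing alphabet, symbol sequence, first-order transition
#' matrix and chunk inventory; adjacent levels are connected by up/down
#' link matrices.
#'
#' @slot env internal state environment.
#' @export
setClass("IdyotMemory", representation(env = "environment"))

#' Geometric conceptual space
#'
#' A Euclidean space whose labelled seed points induce a Voronoi
#' tessellation, optionally modified by a gap between regions and by
#' expectation-driven boundary offsets; regions give symbols their
#' semantics.
#'
#' @slot env internal state environment (seed matrix, symbols, config).
#' @export
setClass("ConceptualSpace", representation(env = "environment"))
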