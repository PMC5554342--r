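## Sentence neural blackboard.
##
## Every element is realised as populations and links in one RateNetwork:
##   - one in-situ concept assembly (a single population) per word;
##   - structure assemblies: a main population plus one population per role
##     sub-assembly, with a bidirectional pair of gating circuits between
##     the main and each sub (3 populations per circuit: relay X, tonically
##     active inhibitor i, disinhibitor di driven by control);
##   - connection nodes, one per bindable pair, each holding a WM population,
##     an entry gating circuit (co-activity ignites the WM) and two
##     directional gating circuits disinhibited by the WM.
##
## Accounting: 3 populations per gating circuit, 1 per WM, 1 per main, sub
## or concept population; a connection node therefore contributes 10.

.bbKindRoles <- list(
  S   = c("n", "v"),
  N   = c("n", "t", "nm", "na", "pn"),
  V   = c("v", "t", "va", "pv"),
  Aux = "va",
  Adj = c("na", "ad"),
  Adv = "ad",
  Num = "nm",
  PP  = c("pv", "pn"))

.bbCategoryKind <- c(noun = "N", verb = "V", localizer = "V", aux = "Aux",
                     adj = "Adj", adv = "Adv", num = "Num",
                     preposition = "PP")

#' Default bindable role pairs
#'
#' The connection matrices instantiated by [makeBlackboard()]: sentence
#' assemblies bind nouns through `n` and verbs through `v`, verbs take
#' themes (`t`), auxiliaries (`va`) and prepositional attachments (`pv`),
#' nouns take numerators (`nm`), adjectives (`na`) and preposition objects
#' (`pn`), and adverbs attach to adjectives (`ad`).
#'
#' @return data.frame with columns `kindA`, `kindB`, `role`.
#' @export
defaultRolePairs <- function() {
  data.frame(
    kindA = c("S", "S", "V", "V", "N",   "N",   "Adj", "V",  "PP"),
    kindB = c("N", "V", "N", "Aux", "Num", "Adj", "Adv", "PP", "N"),
    role  = c("n", "v", "t", "va",  "nm",  "na",  "ad",  "pv", "pn"),
    stringsAsFactors = FALSE)
}

#' Blackboard tuning parameters
#'
#' @param wRelayIn weight from a source assembly onto a gating-circuit
#'   relay (and from the relay onto its target).
#' @param wInhib magnitude of the inhibitory weights `i -> X` and
#'   `di -> i`.
#' @param wEntryWM weight from the entry relay onto the WM population.
#' @param wWMGate weight from a WM population onto the disinhibitors of its
#'   directional circuits.
#' @param selfWM recurrent weight of WM, concept and main populations;
#'   2.0 makes them bistable (stable rest, stable reverberating state)
#'   under the default sigmoid.
#' @param biasInhib tonic drive of gating-circuit inhibitors.
#' @param ignitionThreshold co-activity level treated as supra-threshold by
#'   [bindIfCoactive()] and by binding queries.  The saturating rate
#'   equation caps sustained feed-forward activity near 0.47, so the
#'   default sits below steady drive (~0.42) and above transients.
#' @param wmActiveThreshold WM activity above which a binding counts as
#'   held.
#' @return named list of parameters.
#' @export
blackboardConfig <- function(wRelayIn = 2.5, wInhib = 4, wEntryWM = 1.2,
                             wWMGate = 2, selfWM = 2, biasInhib = 1,
                             ignitionThreshold = 0.35,
                             wmActiveThreshold = 0.2) {
  list(wRelayIn = wRelayIn, wInhib = wInhib, wEntryWM = wEntryWM,
       wWMGate = wWMGate, selfWM = selfWM, biasInhib = biasInhib,
       ignitionThreshold = ignitionThreshold,
       wmActiveThreshold = wmActiveThreshold)
}

## Add one gating circuit src -> tgt; returns the di id.  The di population
## may be driven externally (control-gated circuits), by a WM population
## (binding-gated circuits), or by a third assembly (entry circuits).
## diThreshold/diGain allow an effective AND over several di inputs.
.addGatingCircuit <- function(net, cfg, tag, src, tgt,
                              diThreshold = 0.5, diGain = 4) {
  x <- paste0(tag, ":X"); i <- paste0(tag, ":i"); di <- paste0(tag, ":di")
  addPopulation(net, x)
  addPopulation(net, i, bias = cfg$biasInhib)
  addPopulation(net, di, threshold = diThreshold, gain = diGain)
  addLink(net, src, x, cfg$wRelayIn)
  addLink(net, i, x, -cfg$wInhib)
  addLink(net, di, i, -cfg$wInhib)
  addLink(net, x, tgt, cfg$wRelayIn)
  di
}

## Connection node binding populations a and b: entry circuit (a -> WM,
## disinhibited by b) plus two directional circuits (a -> b and b -> a)
## disinhibited by the WM.  extraGateDrive names an AND-condition: when
## given, directional di's additionally require that external control
## drive (used on word<->main nodes to keep bound words from re-exciting
## their assemblies outside retrieval).
.addConnectionNode <- function(bb, nodeId, a, b, roleA = NA, roleB = NA,
                               kindA = NA, kindB = NA, type = "sub",
                               dirGateControl = FALSE) {
  e <- bb@env; net <- e$net; cfg <- e$config
  wm <- paste0("wm:", nodeId)
  addPopulation(net, wm, selfWeight = cfg$selfWM)
  dientry <- .addGatingCircuit(net, cfg, paste0("e:", nodeId), a, wm)
  addLink(net, b, dientry, 2)
  ## relay of the entry circuit feeds the WM at reduced weight
  xe <- paste0("e:", nodeId, ":X")
  ## rescale: the circuit wired X->wm with wRelayIn; adjust by a parallel
  ## inhibitory correction is clumsy, so wire entry target weight directly:
  ## remove is not supported; instead .addGatingCircuit linked x->wm with
  ## wRelayIn.  Compensate to the configured entry weight:
  addLink(net, xe, wm, cfg$wEntryWM - cfg$wRelayIn)
  if (dirGateControl) {
    ## steep, high-threshold disinhibitor: an effective AND of the node's
    ## WM (weight 1) and the global word-flow control drive (0.5) -- each
    ## alone leaves the circuit fully blocked
    d1 <- .addGatingCircuit(net, cfg, paste0("d1:", nodeId), a, b,
                            diThreshold = 0.8, diGain = 10)
    d2 <- .addGatingCircuit(net, cfg, paste0("d2:", nodeId), b, a,
                            diThreshold = 0.8, diGain = 10)
    addLink(net, wm, d1, 1); addLink(net, wm, d2, 1)
    e$wordInDis <- c(e$wordInDis, d1)   # word -> main direction
    e$wordOutDis <- c(e$wordOutDis, d2) # main -> word direction
  } else {
    d1 <- .addGatingCircuit(net, cfg, paste0("d1:", nodeId), a, b)
    d2 <- .addGatingCircuit(net, cfg, paste0("d2:", nodeId), b, a)
    addLink(net, wm, d1, cfg$wWMGate); addLink(net, wm, d2, cfg$wWMGate)
  }
  k <- e$nNodes + 1L
  e$nNodes <- k
  e$nodes[[k]] <- list(id = nodeId, type = type, a = a, b = b,
                       roleA = roleA, roleB = roleB,
                       kindA = kindA, kindB = kindB, wm = wm)
  invisible(nodeId)
}

#' Construct a sentence blackboard
#'
#' Instantiates one concept assembly per vocabulary word, a pool of
#' structure assemblies per kind (with the full role set of that kind and
#' bidirectional main-sub gating circuits), connection matrices between
#' words and the mains of their kind, and connection matrices for every
#' bindable role pair present in the pools.
#'
#' @param vocabulary named character vector: word -> category (one of
#'   `noun`, `verb`, `localizer`, `aux`, `adj`, `adv`, `num`,
#'   `preposition`).
#' @param poolSizes named integer vector: structure-assembly kind -> pool
#'   size.  Kinds default to one assembly for every kind needed by the
#'   vocabulary plus one `S` assembly.
#' @param rolePairs data.frame as [defaultRolePairs()]; matrices are built
#'   for pairs whose two kinds both have pools.
#' @param config list from [blackboardConfig()].
#' @return a [Blackboard-class].
#' @export
makeBlackboard <- function(vocabulary, poolSizes = NULL,
                           rolePairs = defaultRolePairs(),
                           config = blackboardConfig()) {
  if (length(vocabulary) == 0L) stop("vocabulary must not be empty", call. = FALSE)
  if (is.null(names(vocabulary))) stop("vocabulary must be named", call. = FALSE)
  bad <- setdiff(unname(vocabulary), names(.bbCategoryKind))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  wordKind <- .bbCategoryKind[unname(vocabulary)]
  if (is.null(poolSizes)) {
    poolSizes <- table(wordKind)
    poolSizes <- stats::setNames(as.integer(poolSizes), names(poolSizes))
    poolSizes["S"] <- 1L
  }
  if (any(poolSizes < 1L)) stop("pool sizes must be >= 1", call. = FALSE)

  e <- new.env(parent = emptyenv())
  e$net <- RateNetwork()
  e$config <- config
  e$vocabulary <- vocabulary
  e$wordKind <- stats::setNames(wordKind, names(vocabulary))
  e$poolSizes <- poolSizes
  e$nodes <- list(); e$nNodes <- 0L
  e$wordInDis <- character(); e$wordOutDis <- character()
  e$roleDis <- list()       # [[kind]][[role]] -> di ids (both directions)
  e$assemblies <- data.frame(kind = character(), index = integer(),
                             main = character(), stringsAsFactors = FALSE)
  e$recruited <- logical(0)
  e$quenched <- logical(0)
  e$assemblyWord <- character(0)  # word whose interval recruited it
  e$gateDrive <- new.env(parent = emptyenv())
  bb <- new("Blackboard", env = e)
  net <- e$net; cfg <- config

  for (w in names(vocabulary))
    addPopulation(net, paste0("w:", w), selfWeight = cfg$selfWM)

  for (kind in names(poolSizes)) {
    roles <- .bbKindRoles[[kind]]
    if (is.null(roles)) stop("unknown kind: ", kind, call. = FALSE)
    e$roleDis[[kind]] <- stats::setNames(
      replicate(length(roles), character(), simplify = FALSE), roles)
    for (i in seq_len(poolSizes[[kind]])) {
      main <- paste0(kind, i)
      addPopulation(net, main, selfWeight = cfg$selfWM)
      e$assemblies <- rbind(e$assemblies,
                            data.frame(kind = kind, index = i, main = main,
                                       stringsAsFactors = FALSE))
      for (r in roles) {
        sub <- paste0(main, "-", r)
        addPopulation(net, sub)
        d1 <- .addGatingCircuit(net, cfg, paste0("g:", main, ">", sub),
                                main, sub)
        d2 <- .addGatingCircuit(net, cfg, paste0("g:", sub, ">", main),
                                sub, main)
        e$roleDis[[kind]][[r]] <- c(e$roleDis[[kind]][[r]], d1, d2)
      }
    }
  }
  e$recruited <- logical(nrow(e$assemblies))
  e$quenched <- logical(nrow(e$assemblies))
  e$assemblyWord <- rep(NA_character_, nrow(e$assemblies))
  e$recruitStamp <- integer(nrow(e$assemblies))

  ## word <-> main connection matrices, per kind
  for (w in names(vocabulary)) {
    kind <- e$wordKind[[w]]
    if (!kind %in% names(poolSizes)) next
    for (i in seq_len(poolSizes[[kind]])) {
      main <- paste0(kind, i)
      .addConnectionNode(bb, paste0("w:", w, "~", main),
                         a = paste0("w:", w), b = main,
                         kindB = kind, type = "word", dirGateControl = TRUE)
    }
  }

  ## sub <-> sub connection matrices per bindable role pair
  for (p in seq_len(nrow(rolePairs))) {
    ka <- rolePairs$kindA[p]; kb <- rolePairs$kindB[p]; r <- rolePairs$role[p]
    if (!(ka %in% names(poolSizes)) || !(kb %in% names(poolSizes))) next
    for (i in seq_len(poolSizes[[ka]])) for (j in seq_len(poolSizes[[kb]])) {
      sa <- paste0(ka, i, "-", r); sb <- paste0(kb, j, "-", r)
      .addConnectionNode(bb, paste0(sa, "~", sb), a = sa, b = sb,
                         roleA = r, roleB = r, kindA = ka, kindB = kb,
                         type = "sub")
    }
  }
  bb
}

#' Closed-form population count of a blackboard layout
#'
#' Independent arithmetic audit of the element accounting: one population
#' per concept, main and sub assembly, three per gating circuit, one per
#' WM; each main-sub connection contributes two gating circuits and each
#' connection node one WM plus three circuits.
#'
#' @inheritParams makeBlackboard
#' @return expected number of populations.
#' @export
expectedPopulationCount <- function(vocabulary, poolSizes = NULL,
                                    rolePairs = defaultRolePairs()) {
  wordKind <- .bbCategoryKind[unname(vocabulary)]
  if (is.null(poolSizes)) {
    poolSizes <- table(wordKind)
    poolSizes <- stats::setNames(as.integer(poolSizes), names(poolSizes))
    poolSizes["S"] <- 1L
  }
  nConcept <- length(vocabulary)
  nAsm <- sum(vapply(names(poolSizes), function(k)
    poolSizes[[k]] * (1L + 7L * length(.bbKindRoles[[k]])), numeric(1)))
  nWordNodes <- sum(vapply(unname(wordKind), function(k)
    if (k %in% names(poolSizes)) poolSizes[[k]] else 0L, numeric(1)))
  keep <- rolePairs$kindA %in% names(poolSizes) &
    rolePairs$kindB %in% names(poolSizes)
  nSubNodes <- sum(poolSizes[rolePairs$kindA[keep]] *
                     poolSizes[rolePairs$kindB[keep]])
  nConcept + nAsm + 10L * (nWordNodes + nSubNodes)
}

#' @rdname populationCount
#' @export
blackboardNetwork <- function(bb) bb@env$net

#' Number of populations on a blackboard
#'
#' @param bb a [Blackboard-class].
#' @return integer count (see [expectedPopulationCount()] for the
#'   closed form it must equal).
#' @export
populationCount <- function(bb) nPopulations(bb@env$net)

#' Open or close the main-sub gates of a role
#'
#' Drives (or releases) the disinhibitor populations of the gating
#' circuits between every main assembly of `kind` and its `role`
#' sub-assembly, in both directions, mirroring a control circuit that
#' activates all di populations for that syntactic operation.
#'
#' @param bb a [Blackboard-class].
#' @param kind structure-assembly kind.
#' @param role role valid for that kind.
#' @param open logical: `TRUE` to drive the gates, `FALSE` to release them.
#' @return `bb`, invisibly.
#' @export
openRoleGates <- function(bb, kind, role, open = TRUE) {
  e <- bb@env
  dis <- e$roleDis[[kind]][[role]]
  if (is.null(dis))
    stop("invalid kind/role: ", kind, "/", role, call. = FALSE)
  if (open) for (d in dis) e$gateDrive[[d]] <- 1
  else suppressWarnings(rm(list = dis, envir = e$gateDrive))
  invisible(bb)
}

#' @rdname openRoleGates
#' @param direction `"in"` (word to main), `"out"` (main to word) or
#'   `"both"`.
#' @details `openWordGates` controls the extra AND-condition on the
#'   directional circuits of word-main connection nodes: even for a bound
#'   pair, activation only flows between a word and its assembly while the
#'   corresponding direction is enabled (retrieval opens it; parsing leaves
#'   it closed so re-activated words do not re-excite consumed assemblies).
#' @export
openWordGates <- function(bb, direction = "both", open = TRUE) {
  e <- bb@env
  dis <- switch(direction,
                "in" = e$wordInDis, "out" = e$wordOutDis,
                both = c(e$wordInDis, e$wordOutDis),
                stop("direction must be in/out/both", call. = FALSE))
  if (open) for (d in dis) e$gateDrive[[d]] <- 0.5
  else suppressWarnings(rm(list = dis, envir = e$gateDrive))
  invisible(bb)
}

## Current persistent control drives as schedule rows on [from, to).
.gateDriveSchedule <- function(bb, from, to) {
  e <- bb@env
  ids <- ls(e$gateDrive)
  if (!length(ids))
    return(data.frame(id = character(), onset = numeric(),
                      offset = numeric(), amplitude = numeric()))
  data.frame(id = ids, onset = from, offset = to,
             amplitude = vapply(ids, function(i) e$gateDrive[[i]], numeric(1)),
             row.names = NULL)
}

#' Advance blackboard dynamics
#'
#' Steps the underlying network for `ms` milliseconds under the currently
#' open gates plus any extra external schedule.
#'
#' @param bb a [Blackboard-class].
#' @param ms duration (ms).
#' @param schedule optional extra schedule (times relative to now).
#' @param dt integration step (ms).
#' @return the [ActivityTrace-class] of the advance, invisibly.
#' @export
advanceBlackboard <- function(bb, ms, schedule = NULL, dt = 1) {
  sch <- .gateDriveSchedule(bb, 0, ms)
  if (!is.null(schedule) && nrow(schedule)) sch <- rbind(sch, schedule)
  invisible(runNetwork(bb@env$net, sch, duration = ms, dt = dt))
}

#' Recruit the next free structure assembly of a kind
#'
#' Deterministically selects the lowest-index assembly of `kind` not yet
#' recruited, marks it recruited and returns its main id.  Exhausting the
#' pool is an explicit error.
#'
#' @param bb a [Blackboard-class].
#' @param kind assembly kind.
#' @param word optional word whose presentation recruited the assembly
#'   (recorded for script bookkeeping).
#' @return main population id.
#' @export
recruitAssembly <- function(bb, kind, word = NA_character_) {
  e <- bb@env
  cand <- which(e$assemblies$kind == kind & !e$recruited)
  if (!length(cand))
    stop("structure-assembly pool exhausted for kind ", kind, call. = FALSE)
  i <- cand[which.min(e$assemblies$index[cand])]
  e$recruited[i] <- TRUE
  e$assemblyWord[i] <- word
  e$assemblies$main[i]
}

#' Ignite WM populations of co-active connection nodes
#'
#' Scans every connection node; where both bound endpoints exceed the
#' ignition threshold and the WM population is not yet active, the WM is
#' kicked into its reverberating state.  (In a full dynamical run the entry
#' gating circuit does this on its own; this operation is the discrete
#' counterpart used for stepwise parsing and for audits.)
#'
#' @param bb a [Blackboard-class].
#' @param threshold co-activity threshold (defaults to the configured
#'   ignition threshold).
#' @return character vector of newly ignited node ids.
#' @export
bindIfCoactive <- function(bb, threshold = NULL) {
  e <- bb@env
  if (is.null(threshold)) threshold <- e$config$ignitionThreshold
  A <- activities(e$net)
  new <- character()
  for (nd in e$nodes[seq_len(e$nNodes)]) {
    if (A[[nd$a]] >= threshold && A[[nd$b]] >= threshold &&
        A[[nd$wm]] < e$config$wmActiveThreshold) {
      setActivities(e$net, stats::setNames(0.45, nd$wm))
      new <- c(new, nd$id)
    }
  }
  new
}

## Statically ignite a specific node's WM (used by the bridge compiler).
.igniteNode <- function(bb, nodeId) {
  e <- bb@env
  for (nd in e$nodes[seq_len(e$nNodes)]) {
    if (nd$id == nodeId) {
      setActivities(e$net, stats::setNames(0.45, nd$wm))
      return(invisible(nodeId))
    }
  }
  stop("no such connection node: ", nodeId, call. = FALSE)
}

#' Read the bound structure off a blackboard
#'
#' One triple per active WM population: word-main bindings give
#' `(word, "word", assembly)` edges and sub-sub bindings give
#' `(assemblyA, role, assemblyB)` edges.  Together they form the sentence's
#' connection path.
#'
#' @param bb a [Blackboard-class].
#' @return a [BindingGraph-class].
#' @export
boundStructure <- function(bb) {
  e <- bb@env
  A <- activities(e$net)
  thr <- e$config$wmActiveThreshold
  va <- character(); vb <- character(); role <- character()
  for (nd in e$nodes[seq_len(e$nNodes)]) {
    if (A[[nd$wm]] >= thr) {
      if (nd$type == "word") {
        va <- c(va, sub("^w:", "", nd$a)); vb <- c(vb, nd$b)
        role <- c(role, "word")
      } else {
        va <- c(va, sub("-[a-z]+$", "", nd$a))
        vb <- c(vb, sub("-[a-z]+$", "", nd$b))
        role <- c(role, nd$roleA)
      }
    }
  }
  edges <- data.frame(a = va, role = role, b = vb, stringsAsFactors = FALSE)
  ids <- unique(c(edges$a, edges$b))
  isWord <- ids %in% names(e$vocabulary)
  vertices <- data.frame(
    id = ids,
    type = ifelse(isWord, "word", "assembly"),
    label = ifelse(isWord, ids, sub("[0-9]+$", "", ids)),
    stringsAsFactors = FALSE)
  new("BindingGraph", vertices = vertices, edges = edges)
}

#' Content-addressable retrieval from the bound blackboard
#'
#' Activates the cue word's in-situ assembly, opens the word gates and the
#' main-sub gates of every role on the role path (for every kind carrying
#' that role), lets activation flow through the WM-bound connection path,
#' and returns the words whose concept assemblies become active at the far
#' end: the words whose assembly carries an active sub-assembly of the
#' final role on the path, excluding the cue itself.
#'
#' The probe is non-destructive: network activity is restored afterwards.
#'
#' @param bb a [Blackboard-class].
#' @param cue word in the vocabulary.
#' @param rolePath character vector of roles, e.g. `c("n","v","pv","pn")`.
#' @param settleMs settling time per hop group (total run is
#'   `settleMs + 150` ms).
#' @return character vector of retrieved words (possibly empty).
#' @export
retrieveWords <- function(bb, cue, rolePath, settleMs = 600) {
  e <- bb@env
  if (!cue %in% names(e$vocabulary))
    stop("cue not in vocabulary: ", cue, call. = FALSE)
  snapshotA <- activities(e$net)
  snapshotGates <- as.list(e$gateDrive)
  on.exit({
    setActivities(e$net, snapshotA)
    rm(list = ls(e$gateDrive), envir = e$gateDrive)
    for (g in names(snapshotGates)) e$gateDrive[[g]] <- snapshotGates[[g]]
  })
  openWordGates(bb, "both", TRUE)
  for (r in rolePath)
    for (kind in names(e$roleDis))
      if (r %in% names(e$roleDis[[kind]])) openRoleGates(bb, kind, r, TRUE)
  sch <- data.frame(id = paste0("w:", cue), onset = 0, offset = 150,
                    amplitude = 1)
  advanceBlackboard(bb, settleMs + 150, schedule = sch)
  A <- activities(e$net)
  thr <- e$config$ignitionThreshold
  finalRole <- rolePath[length(rolePath)]
  prevRole <- if (length(rolePath) > 1) rolePath[length(rolePath) - 1]
              else NA_character_
  subActive <- function(main, role) {
    id <- paste0(main, "-", role)
    !is.null(e$net@env$idx[[id]]) && A[[id]] >= thr
  }
  out <- character()
  for (nd in e$nodes[seq_len(e$nNodes)]) {
    if (nd$type != "word") next
    w <- sub("^w:", "", nd$a)
    if (w == cue) next
    ## the answer's assembly was reached through the final role of the
    ## path: its final-role sub is active, and it is an endpoint, not a
    ## way-station (those also carry the previous role's sub)
    if (A[[nd$wm]] >= e$config$wmActiveThreshold &&
        A[[nd$a]] >= thr &&
        subActive(nd$b, finalRole) &&
        (is.na(prevRole) || !subActive(nd$b, prevRole)))
      out <- c(out, w)
  }
  unique(out)
}

#' Reset all bindings and activity
#'
#' Clears every population back to its baseline, releases all gates and
#' forgets recruitments.  (WM bindings do not decay on their own at
#' sentence end; this is the explicit clear.)
#'
#' @param bb a [Blackboard-class].
#' @return `bb`, invisibly.
#' @export
resetBindings <- function(bb) {
  e <- bb@env
  n <- e$net@env$n
  e$net@env$A[seq_len(n)] <- e$net@env$baseline[seq_len(n)]
  rm(list = ls(e$gateDrive), envir = e$gateDrive)
  e$recruited[] <- FALSE
  e$quenched[] <- FALSE
  e$assemblyWord[] <- NA_character_
  e$recruitStamp[] <- 0L
  invisible(bb)
}

#' Serialize blackboard topology and binding state to JSON
#'
#' @param bb a [Blackboard-class].
#' @param path optional file.
#' @return JSON string (invisibly if written).
#' @export
blackboardToJSON <- function(bb, path = NULL) {
  e <- bb@env
  A <- activities(e$net)
  thr <- e$config$wmActiveThreshold
  nodes <- e$nodes[seq_len(e$nNodes)]
  js <- jsonlite::toJSON(list(
    vocabulary = as.list(e$vocabulary),
    poolSizes = as.list(e$poolSizes),
    populationCount = populationCount(bb),
    assemblies = e$assemblies,
    activeWM = vapply(nodes, function(nd) nd$id, character(1))[
      vapply(nodes, function(nd) A[[nd$wm]] >= thr, logical(1))]),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Export a binding graph as an edge-list CSV
#'
#' Columns `element_a,role,element_b`.
#'
#' @param graph a [BindingGraph-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBindingGraph <- function(graph, path) {
  df <- graph@edges
  names(df) <- c("element_a", "role", "element_b")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

setMethod("show", "Blackboard", function(object) {
  e <- object@env
  cat("Blackboard:", length(e$vocabulary), "words,",
      nrow(e$assemblies), "structure assemblies,",
      e$nNodes, "connection nodes,",
      populationCount(object), "populations\n")
})

setMethod("show", "BindingGraph", function(object) {
  cat("BindingGraph:", nrow(object@vertices), "vertices,",
      nrow(object@edges), "bindings\n")
  if (nrow(object@edges)) {
    df <- object@edges
    cat(paste0("  ", df$a, " -[", df$role, "]- ", df$b), sep = "\n")
  }
})
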