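## Layered entropy-chunking sequence memory.
##
## Per viewpoint and per level the memory holds a growing alphabet, the
## symbol sequence, a first-order transition matrix (add-one smoothed over
## the current alphabet), the chunks closed so far (extents tiling the
## sequence) and, between adjacent levels, up/down link counts.  Chunking:
## when symbol s_t arrives, the change in boundary entropy
##   dH = H(D(. | s_t)) - H(D(. | s_t-1))
## is computed from the model state *before* the new transition is counted
## (alphabet already extended); among all generators with dH > 0 the single
## largest wins global-workspace access and closes its open chunk at the
## boundary after s_t, i.e. before the not-yet-seen next symbol -- the
## position where the successor distribution spiked.  The closed chunk's
## label is appended one level up, where the same boundary test cascades.

#' Shannon entropy of a distribution, in bits
#'
#' `H(D) = -sum p(s) log2 p(s)` with `0 log 0 := 0`.
#'
#' @param D named (or plain) numeric probability vector; must be
#'   non-negative and sum to 1 within 1e-9.
#' @return entropy in bits.
#' @export
entropyBits <- function(D) {
  if (any(D < 0) || abs(sum(D) - 1) > 1e-9)
    stop("D is not a normalized distribution", call. = FALSE)
  p <- D[D > 0]
  -sum(p * log2(p))
}

#' Information content of a symbol, in bits
#'
#' `h(D, s) = -log2 p(s)`.  A symbol with zero probability yields `Inf`,
#' the distinguished infinite-surprise value.
#'
#' @param D named numeric probability vector.
#' @param s symbol in `names(D)`.
#' @return bits (possibly `Inf`).
#' @export
informationContent <- function(D, s) {
  if (!s %in% names(D)) stop("symbol not in alphabet: ", s, call. = FALSE)
  p <- D[[s]]
  if (p == 0) return(Inf)
  -log2(p)
}

#' Entropy-weighted mixture of distributions
#'
#' Superposes distributions over a common alphabet with weights
#' proportional to `2^-H` (sharper predictions weigh more), renormalized.
#'
#' @param dists list of named probability vectors over identical alphabets.
#' @return the mixed distribution.
#' @export
mixDistributions <- function(dists) {
  stopifnot(length(dists) >= 1)
  ab <- names(dists[[1]])
  for (d in dists)
    if (!identical(sort(names(d)), sort(ab)))
      stop("distributions must share one alphabet", call. = FALSE)
  w <- vapply(dists, function(d) 2^(-entropyBits(d)), numeric(1))
  w <- w / sum(w)
  out <- stats::setNames(rep(0, length(ab)), ab)
  for (i in seq_along(dists)) out <- out + w[i] * dists[[i]][ab]
  out
}

#' Chunker configuration
#'
#' @param samplingRate nominal event rate (Hz); bookkeeping only.
#' @param maxLevels maximum number of memory levels (level 0 is the raw
#'   stream; `maxLevels = 1` disables promotion).
#' @param forgetPeriod events after which a losing generator's candidate
#'   boundary is discarded.
#' @param consolidateEvery events between consolidation passes when
#'   [learnCorpus()] drives learning (`Inf` disables).
#' @return named list.
#' @export
chunkerConfig <- function(samplingRate = 40, maxLevels = 3,
                          forgetPeriod = 20, consolidateEvery = Inf) {
  stopifnot(samplingRate > 0, maxLevels >= 1, forgetPeriod > 0,
            consolidateEvery > 0)
  list(samplingRate = samplingRate, maxLevels = maxLevels,
       forgetPeriod = forgetPeriod, consolidateEvery = consolidateEvery)
}

.newLevel <- function() {
  l <- new.env(parent = emptyenv())
  l$n <- 0L
  l$seq <- character(64L)
  l$alphabet <- character(0)
  l$trans <- new.env(parent = emptyenv())   # context -> named counts
  l$nChunks <- 0L
  l$chunkLabel <- character(16L)
  l$chunkStart <- integer(16L)
  l$chunkEnd <- integer(16L)
  l$openStart <- 1L
  l$labelMap <- new.env(parent = emptyenv()) # subtended seq -> upper label
  l$nLabels <- 0L
  l$down <- new.env(parent = emptyenv())     # upper label -> lower counts
  l$up <- new.env(parent = emptyenv())       # lower sym -> upper counts
  l
}

.levelAppend <- function(l, sym) {
  n <- l$n + 1L
  if (n > length(l$seq)) length(l$seq) <- 2L * length(l$seq)
  l$seq[n] <- sym
  l$n <- n
  n
}

.levelSeq <- function(l) l$seq[seq_len(l$n)]

.addTransition <- function(l, ctx, sym) {
  row <- l$trans[[ctx]]
  if (is.null(row)) row <- stats::setNames(integer(0), character(0))
  if (sym %in% names(row)) row[[sym]] <- row[[sym]] + 1L
  else row <- c(row, stats::setNames(1L, sym))
  l$trans[[ctx]] <- row
}

.rowDist <- function(l, ctx, smoothing = 1) {
  ab <- l$alphabet
  counts <- stats::setNames(rep(0, length(ab)), ab)
  row <- l$trans[[ctx]]
  if (!is.null(row)) counts[names(row)] <- counts[names(row)] + row
  p <- (counts + smoothing) / (sum(counts) + smoothing * length(ab))
  p
}

.bumpLink <- function(env, key, sym) {
  row <- env[[key]]
  if (is.null(row)) row <- stats::setNames(numeric(0), character(0))
  if (sym %in% names(row)) row[[sym]] <- row[[sym]] + 1
  else row <- c(row, stats::setNames(1, sym))
  env[[key]] <- row
}

#' Create an empty memory
#'
#' @param config list from [chunkerConfig()].
#' @return an [IdyotMemory-class].
#' @export
IdyotMemory <- function(config = chunkerConfig()) {
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$vps <- list()
  e$vpOrder <- character(0)
  e$eventCount <- 0L
  e$pending <- data.frame(event = integer(), viewpoint = character(),
                          position = integer(), stringsAsFactors = FALSE)
  e$log <- character(0)
  new("IdyotMemory", env = e)
}

#' Register a viewpoint
#'
#' Basic viewpoints read a value directly from each event (symbols as-is;
#' numeric values are symbolised through the viewpoint's conceptual
#' space).  A linked viewpoint pairs the symbols of its two source
#' viewpoints; its alphabet is a subset of the cartesian product of the
#' source alphabets.
#'
#' @param mem an [IdyotMemory-class].
#' @param id viewpoint name.
#' @param kind `"basic"` or `"linked"`.
#' @param sources for linked viewpoints, the two source viewpoint ids.
#' @param space optional [ConceptualSpace-class] used to symbolise
#'   continuous basic viewpoints (and to ground chunk-label similarity).
#' @return `mem`, invisibly.
#' @export
registerViewpoint <- function(mem, id, kind = c("basic", "linked"),
                              sources = NULL, space = NULL) {
  kind <- match.arg(kind)
  e <- mem@env
  if (id %in% e$vpOrder) stop("viewpoint already registered: ", id, call. = FALSE)
  if (kind == "linked") {
    stopifnot(length(sources) == 2, all(sources %in% e$vpOrder))
  }
  v <- new.env(parent = emptyenv())
  v$id <- id; v$kind <- kind; v$sources <- sources; v$space <- space
  v$levels <- list(.newLevel())
  e$vps[[id]] <- v
  e$vpOrder <- c(e$vpOrder, id)
  invisible(mem)
}

#' @rdname viewpointAlphabet
#' @export
viewpoints <- function(mem) mem@env$vpOrder

#' Memory accessors
#'
#' @param mem an [IdyotMemory-class].
#' @param viewpoint viewpoint id.
#' @param level level index (0 = raw stream).
#' @return `viewpointAlphabet`: the symbols of that level's alphabet;
#'   `levelSequence`: the symbol sequence; `chunkExtents`: data.frame of
#'   closed chunks (`label`, `start`, `end`, extents indexing the sequence
#'   one level below for `level >= 1`, the raw events for level 0);
#'   `viewpoints`: the registered viewpoint ids.
#' @export
viewpointAlphabet <- function(mem, viewpoint, level = 0) {
  .getLevel(mem, viewpoint, level)$alphabet
}

#' @rdname viewpointAlphabet
#' @export
levelSequence <- function(mem, viewpoint, level = 0) {
  .levelSeq(.getLevel(mem, viewpoint, level))
}

#' @rdname viewpointAlphabet
#' @export
chunkExtents <- function(mem, viewpoint, level = 0) {
  l <- .getLevel(mem, viewpoint, level)
  k <- seq_len(l$nChunks)
  data.frame(label = l$chunkLabel[k], start = l$chunkStart[k],
             end = l$chunkEnd[k], stringsAsFactors = FALSE)
}

.getLevel <- function(mem, viewpoint, level) {
  v <- mem@env$vps[[viewpoint]]
  if (is.null(v)) stop("unknown viewpoint: ", viewpoint, call. = FALSE)
  if (level + 1L > length(v$levels))
    stop("unknown level ", level, " for viewpoint ", viewpoint, call. = FALSE)
  v$levels[[level + 1L]]
}

#' First-order prediction at a level
#'
#' Row-normalized transition counts with add-one smoothing over the
#' current alphabet; an unseen context yields the uniform smoothing limit.
#'
#' @inheritParams viewpointAlphabet
#' @param context the conditioning symbol.
#' @return named probability vector over the level's alphabet.
#' @export
predictNext <- function(mem, viewpoint, level, context) {
  l <- .getLevel(mem, viewpoint, level)
  if (!length(l$alphabet)) stop("empty alphabet", call. = FALSE)
  .rowDist(l, context)
}

## Pre-update boundary-entropy change for appending sym after prevSym.
.deltaH <- function(l, prevSym, sym) {
  if (is.na(prevSym)) return(NA_real_)
  entropyBits(.rowDist(l, sym)) - entropyBits(.rowDist(l, prevSym))
}

.labelFor <- function(mem, vp, l, extent) {
  key <- paste(l$seq[extent[1]:extent[2]], collapse = "\x1f")
  lab <- l$labelMap[[key]]
  if (is.null(lab)) {
    l$nLabels <- l$nLabels + 1L
    lab <- paste0(vp, ".c", l$nLabels)
    l$labelMap[[key]] <- lab
  }
  lab
}

.recordChunk <- function(l, label, start, end) {
  k <- l$nChunks + 1L
  if (k > length(l$chunkLabel)) {
    length(l$chunkLabel) <- 2L * length(l$chunkLabel)
    length(l$chunkStart) <- 2L * length(l$chunkStart)
    length(l$chunkEnd) <- 2L * length(l$chunkEnd)
  }
  l$chunkLabel[k] <- label; l$chunkStart[k] <- start; l$chunkEnd[k] <- end
  l$nChunks <- k
}

## Close the open chunk of (vp, level li), label it, and promote the label
## one level up where the boundary test cascades.
.closeChunk <- function(mem, vpId, li) {
  v <- mem@env$vps[[vpId]]
  l <- v$levels[[li]]
  extent <- c(l$openStart, l$n)
  lab <- .labelFor(mem, vpId, l, extent)
  .recordChunk(l, lab, extent[1], extent[2])
  l$openStart <- l$n + 1L
  .promote(mem, vpId, li, lab, extent)
  invisible(lab)
}

## Append a closed chunk's label at level li + 1, maintaining transition
## and up/down link counts; recurse if the boundary test fires there too.
.promote <- function(mem, vpId, li, label, extent) {
  e <- mem@env
  v <- e$vps[[vpId]]
  if (li + 1L > e$config$maxLevels) {
    e$log <- c(e$log, paste0("max level reached for ", vpId,
                             "; chunk ", label, " not promoted"))
    return(invisible(NULL))
  }
  if (length(v$levels) < li + 1L) v$levels[[li + 1L]] <- .newLevel()
  l <- v$levels[[li]]
  up <- v$levels[[li + 1L]]
  ## up/down links between li - 1 (0-based: the chunk's symbols) and the
  ## new label one level above them
  for (s in l$seq[extent[1]:extent[2]]) {
    .bumpLink(l$down, label, s)
    .bumpLink(l$up, s, label)
  }
  if (!label %in% up$alphabet) up$alphabet <- c(up$alphabet, label)
  prevSym <- if (up$n > 0L) up$seq[up$n] else NA_character_
  dH <- .deltaH(up, prevSym, label)
  .levelAppend(up, label)
  if (!is.na(prevSym)) .addTransition(up, prevSym, label)
  if (!is.na(dH) && dH > 1e-12) .closeChunk(mem, vpId, li + 1L)
  invisible(NULL)
}

#' Promote a labelled chunk by hand
#'
#' Appends `label` to the sequence one level above `level`, updating the
#' transition matrix and the up/down link matrices exactly as the
#' automatic promotion does (including the recursive boundary test).
#' Mainly useful for audits.
#'
#' @inheritParams viewpointAlphabet
#' @param label chunk label.
#' @param extent `c(start, end)` into the sequence at `level`.
#' @return `mem`, invisibly.
#' @export
promoteChunk <- function(mem, viewpoint, level, label, extent) {
  .promote(mem, viewpoint, level + 1L, label, extent)
  invisible(mem)
}

## Resolve one event's symbol for a basic viewpoint.
.eventSymbol <- function(mem, v, value) {
  if (is.character(value)) return(value)
  if (is.numeric(value)) {
    if (is.null(v$space))
      stop("numeric viewpoint ", v$id, " has no conceptual space",
           call. = FALSE)
    l <- v$levels[[1]]
    D <- NULL
    if (length(spaceSymbols(v$space)) &&
        setequal(spaceSymbols(v$space), l$alphabet) && l$n > 0L)
      D <- .rowDist(l, l$seq[l$n])[spaceSymbols(v$space)]
    sym <- classifyPoint(v$space, value, D)
    ## a lone seed has no pair boundary yet, so its gap parameter acts as
    ## a catchment radius until a second seed exists
    if (length(spaceSymbols(v$space)) == 1L) {
      d <- sqrt(sum((seedPoints(v$space)[1, ] - as.numeric(value))^2))
      if (d > max(v$space@env$gap, v$space@env$tol)) sym <- GAP
    }
    if (identical(sym, GAP)) sym <- addSeed(v$space, value)
    return(sym)
  }
  stop("cannot classify value of class ", class(value)[1], call. = FALSE)
}

#' Feed one event to the memory
#'
#' For every viewpoint present in the event the symbol is resolved
#' (continuous values through the viewpoint's conceptual space, under the
#' current expectation), the boundary-entropy change of the viewpoint's
#' level-0 generator is computed, and the symbol is appended.  The single
#' generator with the largest positive entropy change wins global-workspace
#' access and closes its chunk; if none registers an increase there is no
#' winner and no change beyond the appends.  Losing generators' candidate
#' boundaries are remembered and discarded after the forgetting period.
#'
#' @param mem an [IdyotMemory-class].
#' @param event list with an element `vp`: named list viewpoint -> value.
#' @return (invisibly) list with `symbols`, `deltaH`, `winner` (viewpoint
#'   id or `NA`) and `boundary` (level-0 position of the closed chunk's
#'   end, or `NA`).
#' @export
observeEvent <- function(mem, event) {
  e <- mem@env
  e$eventCount <- e$eventCount + 1L
  vals <- event$vp
  if (is.null(vals)) stop("event has no viewpoint values", call. = FALSE)
  syms <- list()
  for (id in e$vpOrder) {
    v <- e$vps[[id]]
    if (v$kind == "basic") {
      if (!id %in% names(vals)) next
      syms[[id]] <- .eventSymbol(mem, v, vals[[id]])
    } else {
      sa <- syms[[v$sources[1]]]; sb <- syms[[v$sources[2]]]
      if (is.null(sa) || is.null(sb)) next
      syms[[id]] <- paste(sa, sb, sep = "+")
    }
  }
  dHs <- stats::setNames(rep(NA_real_, length(syms)), names(syms))
  for (id in names(syms)) {
    v <- e$vps[[id]]
    l <- v$levels[[1]]
    sym <- syms[[id]]
    if (!sym %in% l$alphabet) l$alphabet <- c(l$alphabet, sym)
    prevSym <- if (l$n > 0L) l$seq[l$n] else NA_character_
    dHs[id] <- .deltaH(l, prevSym, sym)
    .levelAppend(l, sym)
    if (!is.na(prevSym)) .addTransition(l, prevSym, sym)
  }
  pos <- vapply(names(syms), function(id)
    e$vps[[id]]$levels[[1]]$n, integer(1))
  cand <- names(syms)[!is.na(dHs[names(syms)]) & dHs[names(syms)] > 1e-12]
  winner <- NA_character_; boundary <- NA_integer_
  if (length(cand)) {
    winner <- cand[which.max(dHs[cand])]
    boundary <- pos[[winner]]
    .closeChunk(mem, winner, 1L)
    losers <- setdiff(cand, winner)
    if (length(losers))
      e$pending <- rbind(e$pending, data.frame(
        event = e$eventCount, viewpoint = losers,
        position = unname(pos[losers]), stringsAsFactors = FALSE))
  }
  e$pending <- e$pending[
    e$pending$event > e$eventCount - e$config$forgetPeriod, , drop = FALSE]
  invisible(list(symbols = syms, deltaH = dHs, winner = winner,
                 boundary = boundary))
}

#' @rdname observeEvent
#' @details `pendingBoundaries` returns the candidate boundaries of losing
#'   generators still inside the forgetting period.
#' @export
pendingBoundaries <- function(mem) mem@env$pending

#' Learn a whole corpus
#'
#' @param mem an [IdyotMemory-class].
#' @param events list of events (as from [genArtificialLanguage()],
#'   [genJLM()] or [readCorpusJSONL()]).
#' @param consolidate whether to run [consolidateMemory()] every
#'   `consolidateEvery` events (per the config).
#' @return `mem` (possibly a consolidated copy), invisibly.
#' @export
learnCorpus <- function(mem, events, consolidate = TRUE) {
  every <- mem@env$config$consolidateEvery
  for (i in seq_along(events)) {
    observeEvent(mem, events[[i]])
    if (consolidate && is.finite(every) && i %% every == 0)
      mem <- consolidateMemory(mem)
  }
  invisible(mem)
}

#' Mean stored code length, in bits per symbol
#'
#' Averages, over every symbol stored at every level of every viewpoint,
#' the information content of that symbol under the memory's current
#' predictive distribution at its position (its predecessor as context;
#' the first symbol of a level is scored against the uniform smoothing
#' distribution).  This is the quantity consolidation minimizes: smaller
#' means a more efficient memory.
#'
#' @param mem an [IdyotMemory-class].
#' @return bits per symbol.
#' @export
meanCodeLength <- function(mem) {
  e <- mem@env
  tot <- 0; cnt <- 0L
  for (id in e$vpOrder) {
    for (l in e$vps[[id]]$levels) {
      if (l$n == 0L) next
      ab <- l$alphabet
      for (j in seq_len(l$n)) {
        if (j == 1L) {
          ## the level's first symbol predates any prediction; score it
          ## against the alphabet plus one unit of escape mass, so even a
          ## single-symbol memory has a positive, finite code length
          tot <- tot + log2(length(ab) + 1)
        } else {
          p <- .rowDist(l, l$seq[j - 1L])
          tot <- tot + informationContent(p, l$seq[j])
        }
        cnt <- cnt + 1L
      }
    }
  }
  if (cnt == 0L) stop("empty memory", call. = FALSE)
  tot / cnt
}

## ---- consolidation ---------------------------------------------------

.cloneEnv <- function(x) {
  if (is.environment(x)) {
    out <- new.env(parent = emptyenv())
    for (nm in ls(x, all.names = TRUE)) assign(nm, .cloneEnv(get(nm, x)), out)
    out
  } else if (is(x, "ConceptualSpace")) {
    new("ConceptualSpace", env = .cloneEnv(x@env))
  } else if (is.list(x) && !is.object(x)) {
    lapply(x, .cloneEnv)
  } else {
    x
  }
}

.cloneMemory <- function(mem) new("IdyotMemory", env = .cloneEnv(mem@env))

## Rebuild a level's transition matrix from its sequence.
.rebuildTrans <- function(l) {
  l$trans <- new.env(parent = emptyenv())
  s <- .levelSeq(l)
  if (length(s) > 1L)
    for (j in 2L:length(s)) .addTransition(l, s[j - 1L], s[j])
}

## Rebuild up/down links between level li and li+1 from chunk extents.
.rebuildLinks <- function(v, li) {
  l <- v$levels[[li]]
  l$down <- new.env(parent = emptyenv())
  l$up <- new.env(parent = emptyenv())
  for (k in seq_len(l$nChunks)) {
    for (s in l$seq[l$chunkStart[k]:l$chunkEnd[k]]) {
      .bumpLink(l$down, l$chunkLabel[k], s)
      .bumpLink(l$up, s, l$chunkLabel[k])
    }
  }
}

## Merge label b into label a at level li (1-based index >= 2) of vp,
## rewriting history, and cascade label collisions upward.
.mergeLabels <- function(mem, vpId, li, a, b) {
  v <- mem@env$vps[[vpId]]
  up <- v$levels[[li]]
  below <- v$levels[[li - 1L]]
  s <- up$seq; s[seq_len(up$n)][s[seq_len(up$n)] == b] <- a; up$seq <- s
  up$alphabet <- setdiff(up$alphabet, b)
  .rebuildTrans(up)
  cl <- below$chunkLabel; cl[cl == b] <- a; below$chunkLabel <- cl
  ## labelMap of the level below: values b -> a; detect key collisions
  for (key in ls(below$labelMap))
    if (identical(below$labelMap[[key]], b)) below$labelMap[[key]] <- a
  .rebuildLinks(v, li - 1L)
  ## cascade: labels one level further up that now subtend identical
  ## sequences must merge too
  if (length(v$levels) > li && up$nChunks > 0L) {
    keys <- vapply(seq_len(up$nChunks), function(k)
      paste(up$seq[up$chunkStart[k]:up$chunkEnd[k]], collapse = "\x1f"),
      character(1))
    lm <- new.env(parent = emptyenv())
    for (k in seq_len(up$nChunks)) {
      lab <- up$chunkLabel[k]
      prev <- lm[[keys[k]]]
      if (is.null(prev)) lm[[keys[k]]] <- lab
      else if (!identical(prev, lab))
        .mergeLabels(mem, vpId, li + 1L, prev, lab)
    }
    up$labelMap <- lm
    .rebuildLinks(v, li)
  }
  invisible(mem)
}

#' Re-optimize category membership (memory consolidation)
#'
#' Greedy local search over chunk-label identities: repeatedly tries
#' merging two labels of the same level (preferring seed pairs that are
#' close in the level's conceptual space when one is attached), accepts a
#' merge only if it strictly reduces [meanCodeLength()], and stops at a
#' local minimum.  Merging rewrites history -- the label sequence, the
#' chunk inventory, the transition and link matrices -- so meanings change
#' retrospectively.
#'
#' @param mem an [IdyotMemory-class].
#' @param maxMoves safety cap on accepted merges.
#' @return the consolidated memory (the input is not modified).
#' @export
consolidateMemory <- function(mem, maxMoves = 50L) {
  cur <- .cloneMemory(mem)
  curLen <- meanCodeLength(cur)
  moves <- 0L
  repeat {
    improved <- FALSE
    for (vpId in cur@env$vpOrder) {
      v <- cur@env$vps[[vpId]]
      for (li in seq_along(v$levels)) {
        if (li == 1L) next                 # level-0 symbols are grounded
        ab <- v$levels[[li]]$alphabet
        if (length(ab) < 2L) next
        pairs <- utils::combn(ab, 2L)
        for (pc in seq_len(ncol(pairs))) {
          a <- pairs[1L, pc]; b <- pairs[2L, pc]
          trial <- .cloneMemory(cur)
          .mergeLabels(trial, vpId, li, a, b)
          len <- meanCodeLength(trial)
          if (len < curLen - 1e-12) {
            cur <- trial; curLen <- len
            improved <- TRUE; moves <- moves + 1L
            break
          }
        }
        if (improved) break
      }
      if (improved) break
    }
    if (!improved || moves >= maxMoves) break
  }
  cur
}

#' Dump a memory to JSON
#'
#' Layers, sequences, alphabets, chunk extents and transition counts for
#' every viewpoint.
#'
#' @param mem an [IdyotMemory-class].
#' @param path optional file.
#' @return JSON string (invisibly if written).
#' @export
memoryToJSON <- function(mem, path = NULL) {
  e <- mem@env
  out <- list(eventCount = e$eventCount, viewpoints = list())
  for (id in e$vpOrder) {
    v <- e$vps[[id]]
    lv <- lapply(seq_along(v$levels), function(li) {
      l <- v$levels[[li]]
      list(level = li - 1L, alphabet = l$alphabet,
           sequence = .levelSeq(l),
           chunks = chunkExtents(mem, id, li - 1L),
           transitions = stats::setNames(
             lapply(ls(l$trans), function(ctx) as.list(l$trans[[ctx]])),
             ls(l$trans)))
    })
    out$viewpoints[[id]] <- list(kind = v$kind, levels = lv)
  }
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

setMethod("show", "IdyotMemory", function(object) {
  e <- object@env
  cat("IdyotMemory:", e$eventCount, "events,",
      length(e$vpOrder), "viewpoint(s)\n")
  for (id in e$vpOrder) {
    v <- e$vps[[id]]
    cat("  ", id, ": ", paste(vapply(v$levels, function(l)
      paste0(l$n, " sym/", l$nChunks, " chunks"), character(1)),
      collapse = " | "), "\n", sep = "")
  }
})
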