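## Bridge: compile a chunk hierarchy onto the sentence blackboard.
##
## A chunking is a token sequence plus a set of chunks (level, start, end,
## category) whose extents are token index ranges; level-0 chunks are the
## tokens themselves.  The role map carries the correspondence between
## chunk categories and blackboard kinds, plus the attachment conventions
## (containment roles, argument rules, modifier rules).  One structure
## assembly is recruited per chunk; containment becomes main-sub bindings
## and sibling order becomes role bindings.  Chunk trees learned by the
## memory do not follow any syntactic theory, which is why the mapping is
## explicit, per-corpus configuration rather than something inferred.

.chunkKind <- function(roleMap, category) {
  if (!category %in% names(roleMap$kinds))
    stop("role map does not cover label/category: ", category, call. = FALSE)
  roleMap$kinds[[category]]
}

#' Extract a chunk hierarchy from a learned memory
#'
#' Level-0 symbols in `[from, to]` become token chunks (category = the
#' symbol), and every closed chunk at any level whose extent lies inside
#' the window is included (category = its label).
#'
#' @param mem an [IdyotMemory-class].
#' @param viewpoint viewpoint id.
#' @param from,to level-0 positions delimiting the sentence extent.
#' @return a chunking list (`tokens`, `tokenCats`, `chunks`).
#' @export
chunkTree <- function(mem, viewpoint, from, to) {
  toks <- levelSequence(mem, viewpoint, 0)[from:to]
  chunks <- data.frame(level = 0L, start = seq_along(toks),
                       end = seq_along(toks), category = toks,
                       stringsAsFactors = FALSE)
  v <- mem@env$vps[[viewpoint]]
  span <- list()                     # per level: token span of each symbol
  span[[1]] <- cbind(from:to, from:to)
  li <- 1L
  while (li < length(v$levels)) {
    l <- v$levels[[li]]
    if (l$nChunks == 0L) break
    ext <- chunkExtents(mem, viewpoint, li - 1L)
    lower <- span[[li]]
    ## map chunk extents (positions at level li-1) to token spans
    spanUp <- matrix(NA_integer_, nrow(ext), 2)
    keep <- logical(nrow(ext))
    for (k in seq_len(nrow(ext))) {
      s <- ext$start[k]; eidx <- ext$end[k]
      if (li == 1L) {
        ts <- s; te <- eidx
        ok <- s >= from && eidx <= to
        if (ok) { ts <- s - from + 1L; te <- eidx - from + 1L }
      } else {
        ok <- s <= nrow(lower) && eidx <= nrow(lower)
        if (ok) { ts <- lower[s, 1]; te <- lower[eidx, 2] }
      }
      if (ok && !is.na(ts) && !is.na(te)) {
        keep[k] <- TRUE
        spanUp[k, ] <- c(ts, te)
        chunks <- rbind(chunks, data.frame(
          level = li, start = ts, end = te, category = ext$label[k],
          stringsAsFactors = FALSE))
      }
    }
    span[[li + 1L]] <- spanUp[keep, , drop = FALSE]
    li <- li + 1L
  }
  list(tokens = toks, tokenCats = toks, chunks = chunks)
}

#' Compile a chunk hierarchy into blackboard bindings
#'
#' Recruits one structure assembly per chunk (kind given by the role map),
#' binds each token chunk's word to its assembly, realises chunk
#' containment as role bindings between a parent and the first child of
#' each kind named in the containment rules, and realises sibling order
#' inside each parent through the argument and modifier rules.  Bindings
#' are ignited directly in the connection nodes' WM populations.
#'
#' @param chunking a chunking list (`tokens`, `tokenCats`, `chunks`), as
#'   from [sentenceFixture()] or [chunkTree()].
#' @param roleMap a role map (see [defaultRoleMap()]); `readRoleMap()`
#'   loads one from YAML.
#' @param bb a [Blackboard-class] with sufficient pools; tokens must be in
#'   its vocabulary for word bindings (non-word chunk labels are bound
#'   structurally only).
#' @return list with `graph` (the compiled [BindingGraph-class]) and
#'   `assemblies` (chunk -> main id).
#' @export
compileStructure <- function(chunking, roleMap, bb) {
  ch <- chunking$chunks
  ch <- ch[order(ch$level, ch$start), , drop = FALSE]
  n <- nrow(ch)
  kinds <- vapply(ch$category, function(x) .chunkKind(roleMap, x),
                  character(1))
  mains <- character(n)
  for (i in seq_len(n)) mains[i] <- recruitAssembly(bb, kinds[i])
  ## word bindings for level-0 chunks
  for (i in which(ch$level == 0L)) {
    w <- chunking$tokens[ch$start[i]]
    if (paste0("w:", w) %in% populationIds(blackboardNetwork(bb)))
      .igniteNode(bb, paste0("w:", w, "~", mains[i]))
  }
  ## direct containment: parent at level L, children at level L-1 whose
  ## extent nests inside and is not covered by an intermediate chunk
  bindPair <- function(ka, ra, ia, kb, rb, ib) {
    sa <- paste0(ka, ia, "-", ra); sb <- paste0(kb, ib, "-", rb)
    id1 <- paste0(sa, "~", sb); id2 <- paste0(sb, "~", sa)
    ok <- tryCatch({ .igniteNode(bb, id1); TRUE },
                   error = function(e) FALSE)
    if (!ok) .igniteNode(bb, id2)
    invisible(NULL)
  }
  idxOf <- function(i) sub("^[A-Za-z]+", "", mains[i])
  for (p in which(ch$level > 0L)) {
    kids <- which(ch$level == ch$level[p] - 1L &
                    ch$start >= ch$start[p] & ch$end <= ch$end[p])
    kids <- kids[order(ch$start[kids])]
    if (!length(kids)) next
    ## containment rules
    rules <- roleMap$containment[[ch$category[p]]]
    if (!is.null(rules)) {
      seen <- character(0)
      for (k in kids) {
        kk <- kinds[k]
        if (!kk %in% names(rules)) next
        r <- rules[[kk]]
        if (isTRUE(roleMap$containmentFirstOnly) && kk %in% seen) next
        seen <- c(seen, kk)
        bindPair(kinds[p], r, idxOf(p), kk, r, idxOf(k))
      }
    }
    ## argument rules: each dependent binds its nearest preceding governor
    ar <- roleMap$argRules
    if (!is.null(ar) && nrow(ar)) {
      for (j in seq_along(kids)) {
        dep <- kids[j]
        cand <- ar[ar$dependent == kinds[dep], , drop = FALSE]
        if (!nrow(cand)) next
        best <- NULL; bestPos <- -Inf
        for (j2 in seq_len(j - 1L)) {
          gov <- kids[j2]
          hit <- cand[cand$governor == kinds[gov], , drop = FALSE]
          if (nrow(hit) && ch$start[gov] > bestPos) {
            best <- list(gov = gov, role = hit$role[1])
            bestPos <- ch$start[gov]
          }
        }
        if (!is.null(best))
          bindPair(kinds[best$gov], best$role, idxOf(best$gov),
                   kinds[dep], best$role, idxOf(dep))
      }
    }
    ## modifier rules: each seeker attaches to the nearest target in its
    ## rule's direction
    mr <- roleMap$modRules
    if (!is.null(mr) && nrow(mr)) {
      for (j in seq_along(kids)) {
        seeker <- kids[j]
        rules2 <- mr[mr$seeker == kinds[seeker], , drop = FALSE]
        for (r2 in seq_len(nrow(rules2))) {
          rng <- if (rules2$dir[r2] == "right")
            kids[seq_along(kids) > j] else rev(kids[seq_along(kids) < j])
          hit <- rng[kinds[rng] == rules2$target[r2]]
          if (length(hit))
            bindPair(kinds[seeker], rules2$role[r2], idxOf(seeker),
                     kinds[hit[1]], rules2$role[r2], idxOf(hit[1]))
        }
      }
    }
  }
  list(graph = boundStructure(bb),
       assemblies = stats::setNames(mains, ch$category))
}

#' Label-preserving graph isomorphism with a mismatch report
#'
#' Decides whether two binding graphs are isomorphic under a mapping that
#' preserves vertex labels (the word for word vertices, the kind for
#' assembly vertices) and edge roles, using VF2 on the colored graphs.
#'
#' @param g1,g2 [BindingGraph-class] objects.
#' @return list with `isomorphic` (logical) and `report` (`"ok"` or the
#'   first mismatch found).
#' @export
verifyIsomorphism <- function(g1, g2) {
  lab1 <- sort(g1@vertices$label); lab2 <- sort(g2@vertices$label)
  if (!identical(lab1, lab2))
    return(list(isomorphic = FALSE,
                report = paste0("vertex label multisets differ: {",
                                paste(lab1, collapse = ","), "} vs {",
                                paste(lab2, collapse = ","), "}")))
  er1 <- sort(g1@edges$role); er2 <- sort(g2@edges$role)
  if (!identical(er1, er2))
    return(list(isomorphic = FALSE,
                report = paste0("edge role multisets differ: {",
                                paste(er1, collapse = ","), "} vs {",
                                paste(er2, collapse = ","), "}")))
  mk <- function(g, vcol, ecol) {
    ig <- igraph::graph_from_data_frame(
      g@edges[, c("a", "b")], directed = FALSE,
      vertices = g@vertices[, "id", drop = FALSE])
    list(g = ig,
         vc = vcol[g@vertices$label[match(igraph::V(ig)$name,
                                          g@vertices$id)]],
         ec = ecol[g@edges$role])
  }
  allLabs <- unique(c(g1@vertices$label, g2@vertices$label))
  vcol <- stats::setNames(seq_along(allLabs), allLabs)
  allRoles <- unique(c(g1@edges$role, g2@edges$role))
  ecol <- stats::setNames(seq_along(allRoles), allRoles)
  a <- mk(g1, vcol, ecol); b <- mk(g2, vcol, ecol)
  iso <- igraph::isomorphic(a$g, b$g, method = "vf2",
                            vertex.color1 = a$vc, vertex.color2 = b$vc,
                            edge.color1 = a$ec, edge.color2 = b$ec)
  list(isomorphic = iso,
       report = if (iso) "ok" else
         "same label multisets but no label-preserving isomorphism")
}

#' Read a role map from YAML
#'
#' @param path YAML file with fields `kinds`, `containment`,
#'   `containmentFirstOnly`, `argRules`, `modRules` (the latter two as
#'   lists of records).
#' @return a role map list.
#' @export
readRoleMap <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list(
    kinds = unlist(y$kinds),
    containment = lapply(y$containment, unlist),
    containmentFirstOnly = isTRUE(y$containmentFirstOnly))
  if (!is.null(y$argRules))
    out$argRules <- do.call(rbind, lapply(y$argRules, as.data.frame))
  if (!is.null(y$modRules))
    out$modRules <- do.call(rbind, lapply(y$modRules, as.data.frame))
  out
}

#' @rdname readRoleMap
#' @param roleMap a role map list.
#' @export
writeRoleMap <- function(roleMap, path) {
  y <- list(kinds = as.list(roleMap$kinds),
            containment = lapply(roleMap$containment, as.list),
            containmentFirstOnly = isTRUE(roleMap$containmentFirstOnly))
  if (!is.null(roleMap$argRules))
    y$argRules <- lapply(seq_len(nrow(roleMap$argRules)), function(i)
      as.list(roleMap$argRules[i, ]))
  if (!is.null(roleMap$modRules))
    y$modRules <- lapply(seq_len(nrow(roleMap$modRules)), function(i)
      as.list(roleMap$modRules[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}
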