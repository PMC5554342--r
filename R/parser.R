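## Control circuits: category lexicon, sequence-node reservoir with an
## exact-association readout, stepwise script execution on the blackboard,
## and question answering from the bound structure.
##
## A command script is a list with one step per token; each step carries a
## list of commands drawn from: recruit(kind), open(kind, role),
## close(kind, role), quench(kind, which).  Execution divides each word
## interval into three phases: presentation (word pulse + recruitment),
## binding (role gates opened, WM ignition through the entry circuits),
## and consolidation (gates closed, consumed assemblies quenched).

.parsePhases <- c(present = 70, bind = 80, consolidate = 50)

#' Look up a word's syntactic/semantic category
#'
#' @param word a word.
#' @param lexicon named character vector word -> category.
#' @return the category.
#' @export
categorize <- function(word, lexicon) {
  if (!nzchar(word)) stop("empty word", call. = FALSE)
  if (!word %in% names(lexicon))
    stop("word not in lexicon: ", word, call. = FALSE)
  lexicon[[word]]
}

#' Command-script constructors
#'
#' Helpers building the command vocabulary understood by
#' [executeScript()]: recruit a structure assembly, open/close the
#' main-sub gates of a (kind, role), or quench (withdraw support from) the
#' most recently recruited assembly of a kind and/or its word.
#'
#' @param kind assembly kind.
#' @param role role label.
#' @param which for `cmdQuench`: `"both"`, `"main"` or `"concept"`.
#' @return a command list.
#' @export
cmdRecruit <- function(kind) list(cmd = "recruit", kind = kind)

#' @rdname cmdRecruit
#' @export
cmdOpen <- function(kind, role) list(cmd = "open", kind = kind, role = role)

#' @rdname cmdRecruit
#' @export
cmdClose <- function(kind, role) list(cmd = "close", kind = kind, role = role)

#' @rdname cmdRecruit
#' @export
cmdQuench <- function(kind, which = "both")
  list(cmd = "quench", kind = kind, which = which)

.validCommand <- function(cm) {
  if (!cm$cmd %in% c("recruit", "open", "close", "quench"))
    stop("unknown command: ", cm$cmd, call. = FALSE)
  if (!cm$kind %in% names(.bbKindRoles))
    stop("command references unknown kind: ", cm$kind, call. = FALSE)
  if (cm$cmd %in% c("open", "close") &&
      !cm$role %in% .bbKindRoles[[cm$kind]])
    stop("invalid role ", cm$role, " for kind ", cm$kind, call. = FALSE)
  invisible(TRUE)
}

## Resolve quench targets: most recently recruited assembly of the kind.
.quenchTargets <- function(bb, kind, which) {
  e <- bb@env
  cand <- which(e$assemblies$kind == kind & e$recruited)
  if (!length(cand)) return(character())
  i <- cand[which.max(e$recruitStamp[cand])]
  out <- character()
  if (which %in% c("both", "main")) out <- c(out, e$assemblies$main[i])
  if (which %in% c("both", "concept") && !is.na(e$assemblyWord[i]))
    out <- c(out, paste0("w:", e$assemblyWord[i]))
  out
}

#' Execute a command script on a blackboard
#'
#' Presents `tokens` one per interval while carrying out the per-token
#' commands; every binding arises from WM ignition in the network dynamics
#' (no binding is written symbolically).
#'
#' @param bb a [Blackboard-class].
#' @param tokens character vector of words, all in the vocabulary.
#' @param script list with one element per token, each a list with a
#'   `commands` list (see [cmdRecruit()] and friends).
#' @param interval word presentation interval (ms).
#' @param dt integration step (ms).
#' @return list with `trace` (the concatenated [ActivityTrace-class] of the
#'   whole presentation) and `onsets` (ms of each word onset), invisibly.
#' @export
executeScript <- function(bb, tokens, script, interval = 200, dt = 1) {
  e <- bb@env
  if (length(script) != length(tokens))
    stop("script length must match token count", call. = FALSE)
  if (is.null(e$recruitStamp)) e$recruitStamp <- integer(nrow(e$assemblies))
  ph <- .parsePhases * interval / sum(.parsePhases)
  ## let tonic populations (gating-circuit inhibitors) reach their resting
  ## state before the first word, so the trace starts at equilibrium
  advanceBlackboard(bb, 150, dt = dt)
  times <- list(); acts <- list(); t0 <- 0
  onsets <- (seq_along(tokens) - 1) * interval
  for (k in seq_along(tokens)) {
    w <- tokens[k]
    wid <- paste0("w:", w)
    if (is.null(e$net@env$idx[[wid]]))
      stop("token not in vocabulary: ", w, call. = FALSE)
    cmds <- script[[k]]$commands
    for (cm in cmds) .validCommand(cm)
    ## phase 1: presentation + recruitment
    sch <- data.frame(id = wid, onset = 0, offset = ph[1], amplitude = 1)
    for (cm in cmds) if (cm$cmd == "recruit") {
      main <- recruitAssembly(bb, cm$kind, word = w)
      i <- which(e$assemblies$main == main)
      e$recruitStamp[i] <- max(e$recruitStamp) + 1L
      sch <- rbind(sch, data.frame(id = main, onset = 10, offset = ph[1],
                                   amplitude = 1))
    }
    tr <- advanceBlackboard(bb, ph[1], schedule = sch, dt = dt)
    times[[length(times) + 1L]] <- tr@time + t0; acts[[length(acts) + 1L]] <- tr@activity
    t0 <- t0 + ph[1]
    ## phase 2: binding (gates open)
    for (cm in cmds) if (cm$cmd == "open") openRoleGates(bb, cm$kind, cm$role, TRUE)
    sch <- data.frame(id = wid, onset = 0, offset = ph[2], amplitude = 1)
    tr <- advanceBlackboard(bb, ph[2], schedule = sch, dt = dt)
    times[[length(times) + 1L]] <- tr@time[-1] + t0
    acts[[length(acts) + 1L]] <- tr@activity[-1, , drop = FALSE]
    t0 <- t0 + ph[2]
    ## phase 3: consolidation (gates closed, consumed assemblies quenched)
    sch <- data.frame(id = wid, onset = 0, offset = ph[3], amplitude = 1)
    for (cm in cmds) {
      if (cm$cmd == "close") openRoleGates(bb, cm$kind, cm$role, FALSE)
      if (cm$cmd == "quench")
        for (id in .quenchTargets(bb, cm$kind, cm$which))
          sch <- rbind(sch, data.frame(id = id, onset = 0, offset = ph[3],
                                       amplitude = -3))
    }
    tr <- advanceBlackboard(bb, ph[3], schedule = sch, dt = dt)
    times[[length(times) + 1L]] <- tr@time[-1] + t0
    acts[[length(acts) + 1L]] <- tr@activity[-1, , drop = FALSE]
    t0 <- t0 + ph[3]
  }
  trace <- new("ActivityTrace",
               time = do.call(c, times),
               activity = do.call(rbind, acts))
  invisible(list(trace = trace, onsets = onsets))
}

#' Create an untrained sequence-node reservoir
#'
#' Sequence nodes chain so that the node for token k fires only after the
#' node for token k - 1; the chain state is the presented category n-gram,
#' and the readout is an exact association from chain states (optionally
#' extended by a blackboard-derived role tag) to command scripts or
#' retrieval plans.
#'
#' @return a [Reservoir-class].
#' @export
Reservoir <- function() {
  e <- new.env(parent = emptyenv())
  e$parse <- new.env(parent = emptyenv())
  e$query <- new.env(parent = emptyenv())
  new("Reservoir", env = e)
}

.keyOf <- function(parts) paste(parts, collapse = " ")

#' Train the reservoir readout by exact association
#'
#' Each example associates a key sequence with a value: for
#' `type = "parse"`, a command script; for `type = "query"`, a retrieval
#' plan `list(cue = "lastNoun"|"verb", rolePath = c(...))` keyed by the
#' category pattern including the blackboard role tag.  Training
#' reproduces every pair exactly; keys not seen in training are rejected at
#' use time, and contradictory examples are a training error.
#'
#' @param reservoir a [Reservoir-class].
#' @param examples list of `list(key = <character vector>, type, value)`.
#' @return `reservoir`, invisibly.
#' @export
trainReadout <- function(reservoir, examples) {
  e <- reservoir@env
  for (ex in examples) {
    map <- if (ex$type == "query") e$query else e$parse
    k <- .keyOf(ex$key)
    old <- map[[k]]
    if (!is.null(old) && !identical(old, ex$value))
      stop("contradictory training examples for key: ", k, call. = FALSE)
    map[[k]] <- ex$value
  }
  invisible(reservoir)
}

## Advance the chain: every prefix must extend towards some trained key.
.chainCheck <- function(map, cats) {
  keys <- ls(map)
  for (k in seq_along(cats)) {
    prefix <- .keyOf(cats[seq_len(k)])
    ok <- any(vapply(keys, function(x)
      startsWith(x, prefix) || startsWith(prefix, x), logical(1)))
    if (!ok)
      stop("category sequence not covered by the rule table: ",
           prefix, call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse a sentence onto the blackboard
#'
#' Categorises the tokens, walks the reservoir chain to retrieve the
#' trained command script for the category sequence, and executes it
#' stepwise; category sequences not covered by the rule table are a parse
#' error (never a silent guess).
#'
#' @param tokens character vector of words.
#' @param lexicon named character vector word -> category.
#' @param bb a [Blackboard-class] whose vocabulary covers the tokens.
#' @param reservoir a trained [Reservoir-class]
#'   (default: [defaultReservoir()]).
#' @param interval word presentation interval (ms).
#' @return list with `graph` (the [BindingGraph-class] bound structure),
#'   `trace` and `onsets`.
#' @export
parseSentence <- function(tokens, lexicon, bb,
                          reservoir = defaultReservoir(), interval = 200) {
  if (!length(tokens)) stop("no tokens", call. = FALSE)
  cats <- vapply(tokens, categorize, character(1), lexicon = lexicon)
  .chainCheck(reservoir@env$parse, cats)
  script <- reservoir@env$parse[[.keyOf(cats)]]
  if (is.null(script))
    stop("category sequence not covered by the rule table: ",
         .keyOf(cats), call. = FALSE)
  res <- executeScript(bb, tokens, script, interval = interval)
  list(graph = boundStructure(bb), trace = res$trace, onsets = res$onsets)
}

.roleTagMap <- c(n = "Agent", t = "Theme", pn = "Location", v = "Verb",
                 va = "Aux", nm = "Numerator", na = "Adjective",
                 ad = "Adverb", pv = "Preposition")
.roleTagPriority <- c("n", "t", "pn", "v", "va", "nm", "na", "ad", "pv")

## Role tag of a word read off the bound structure: the highest-priority
## structural role of any assembly the word is bound to.
.wordRoleTag <- function(bb, word) {
  g <- boundStructure(bb)
  mains <- g@edges$b[g@edges$role == "word" & g@edges$a == word]
  if (!length(mains)) return(NULL)
  el <- g@edges[g@edges$role != "word", , drop = FALSE]
  roles <- el$role[el$a %in% mains | el$b %in% mains]
  if (!length(roles)) return(NULL)
  .roleTagMap[[.roleTagPriority[min(match(roles, .roleTagPriority))]]]
}

#' Recognise a question pattern
#'
#' Transforms a wh-question into its general category form and appends the
#' role tag of the cued noun, obtained from the blackboard: the cue's
#' in-situ assembly activates the bound sentence fragment it belongs to,
#' and the tag is the role of that binding (content addressability at
#' work).  A cue with no active binding is an open-query error.
#'
#' @param tokens question tokens (first must be a wh-word).
#' @param lexicon named character vector word -> category.
#' @param bb a [Blackboard-class].
#' @return character vector: the categories followed by the role tag.
#' @export
recognizeQuery <- function(tokens, lexicon, bb) {
  cats <- vapply(tokens, categorize, character(1), lexicon = lexicon)
  if (!cats[1] %in% c("where", "who", "what"))
    stop("not a wh-question: ", tokens[1], call. = FALSE)
  nouns <- tokens[cats == "noun"]
  if (!length(nouns)) stop("no cued noun in query", call. = FALSE)
  cue <- nouns[length(nouns)]
  tag <- .wordRoleTag(bb, cue)
  if (is.null(tag))
    stop(errorCondition(paste0("open query: no active binding for ", cue),
                        class = c("conceptboard_openQuery", "error")))
  c(unname(cats), tag)
}

#' Answer a wh-question from the bound blackboard
#'
#' Runs [recognizeQuery()], looks the resulting pattern up in the
#' reservoir's query readout, and retrieves along the trained role path
#' with [retrieveWords()].  An unanswerable question (no binding for the
#' cue, untrained pattern, or empty retrieval) signals a no-answer
#' condition of class `conceptboard_noAnswer`.
#'
#' @inheritParams recognizeQuery
#' @param reservoir a trained [Reservoir-class].
#' @return the answer word.
#' @export
answerQuestion <- function(tokens, lexicon, bb,
                           reservoir = defaultReservoir()) {
  noAnswer <- function(msg)
    stop(errorCondition(msg, class = c("conceptboard_noAnswer", "error")))
  pattern <- tryCatch(recognizeQuery(tokens, lexicon, bb),
                      conceptboard_openQuery = function(e) NULL)
  if (is.null(pattern)) noAnswer("no answer: cue has no active binding")
  plan <- reservoir@env$query[[.keyOf(pattern)]]
  if (is.null(plan)) noAnswer(paste0("no answer: untrained pattern ",
                                     .keyOf(pattern)))
  cats <- vapply(tokens, categorize, character(1), lexicon = lexicon)
  cue <- switch(plan$cue,
                lastNoun = rev(tokens[cats == "noun"])[1],
                verb = tokens[cats %in% c("verb", "localizer")][1],
                stop("unknown cue selector: ", plan$cue, call. = FALSE))
  words <- retrieveWords(bb, cue, plan$rolePath)
  if (!length(words)) noAnswer("no answer: retrieval came back empty")
  sort(words)[1]
}

setMethod("show", "Reservoir", function(object) {
  cat("Reservoir:", length(ls(object@env$parse)), "parse associations,",
      length(ls(object@env$query)), "query associations\n")
})
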