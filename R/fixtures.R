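## Sentence fixtures and synthetic corpora.
##
## The three fixture sentences pin down one syntactic reading each: a
## locative copular sentence, a transitive sentence with a repeated noun
## (the "problem of two"), and a nine-word sentence exercising every
## structure-assembly kind.  Each fixture carries its tokens, category
## lexicon, parse script, reference binding graph, a hand-specified chunk
## hierarchy and the role map that compiles it.

.fixtureNames <- c("cat-is-on-mat", "cat-sees-cat", "bill-gates")

.refGraph <- function(words, cats, wordAsm, structEdges) {
  edges <- rbind(
    data.frame(a = words, role = "word", b = wordAsm,
               stringsAsFactors = FALSE),
    structEdges)
  ids <- unique(c(edges$a, edges$b))
  isWord <- ids %in% words
  vertices <- data.frame(
    id = ids, type = ifelse(isWord, "word", "assembly"),
    label = ifelse(isWord, ids, sub("[0-9]+$", "", ids)),
    stringsAsFactors = FALSE)
  new("BindingGraph", vertices = vertices, edges = edges)
}

.edge <- function(a, role, b)
  data.frame(a = a, role = role, b = b, stringsAsFactors = FALSE)

#' Default role map for the fixture sentences
#'
#' Maps chunk/token categories to structure-assembly kinds and states the
#' attachment conventions: a sentence chunk binds its first noun child via
#' `n` and its first verb child via `v`; a noun fills the argument slot of
#' its nearest preceding verb (`t`) or preposition (`pn`), preposition
#' winning when nearer; numerators, adjectives and auxiliaries attach
#' forward to the nearest noun/noun/verb (`nm`, `na`, `va`), adverbs
#' forward to the nearest adjective (`ad`), and prepositions backward to
#' the nearest verb (`pv`).
#'
#' @return a role-map list understood by [compileStructure()].
#' @export
defaultRoleMap <- function() {
  list(
    kinds = c(noun = "N", verb = "V", localizer = "V",
              preposition = "PP", aux = "Aux", adj = "Adj",
              adv = "Adv", num = "Num", s = "S"),
    containment = list(s = c(N = "n", V = "v")),
    containmentFirstOnly = TRUE,
    argRules = data.frame(governor = c("V", "PP"), dependent = "N",
                          role = c("t", "pn"), stringsAsFactors = FALSE),
    modRules = data.frame(
      seeker = c("Num", "Adj", "Adv", "Aux", "PP"),
      target = c("N", "N", "Adj", "V", "V"),
      role = c("nm", "na", "ad", "va", "pv"),
      dir = c("right", "right", "right", "right", "left"),
      stringsAsFactors = FALSE))
}

.flatChunking <- function(tokens, cats) {
  n <- length(tokens)
  list(tokens = tokens, tokenCats = cats,
       chunks = rbind(
         data.frame(level = 0L, start = seq_len(n), end = seq_len(n),
                    category = cats, stringsAsFactors = FALSE),
         data.frame(level = 1L, start = 1L, end = n, category = "s",
                    stringsAsFactors = FALSE)))
}

.fixtureData <- function(name) {
  switch(
    name,
    "cat-is-on-mat" = {
      tokens <- c("cat", "is", "on", "mat")
      cats <- c("noun", "localizer", "preposition", "noun")
      script <- list(
        list(commands = list(cmdRecruit("N"))),
        list(commands = list(cmdRecruit("V"), cmdRecruit("S"),
                             cmdOpen("N", "n"), cmdOpen("S", "n"),
                             cmdOpen("V", "v"), cmdOpen("S", "v"),
                             cmdClose("N", "n"), cmdClose("S", "n"),
                             cmdClose("V", "v"), cmdClose("S", "v"),
                             cmdQuench("N"), cmdQuench("S", "main"))),
        list(commands = list(cmdRecruit("PP"),
                             cmdOpen("V", "pv"), cmdOpen("PP", "pv"),
                             cmdClose("V", "pv"), cmdClose("PP", "pv"),
                             cmdQuench("V"))),
        list(commands = list(cmdRecruit("N"),
                             cmdOpen("PP", "pn"), cmdOpen("N", "pn"),
                             cmdClose("PP", "pn"), cmdClose("N", "pn"),
                             cmdQuench("PP"), cmdQuench("N"))))
      ref <- .refGraph(tokens, cats, c("N1", "V1", "PP1", "N2"),
                       rbind(.edge("S1", "n", "N1"), .edge("S1", "v", "V1"),
                             .edge("V1", "pv", "PP1"),
                             .edge("PP1", "pn", "N2")))
      list(tokens = tokens, cats = cats, script = script, ref = ref)
    },
    "cat-sees-cat" = {
      tokens <- c("cat", "sees", "cat")
      cats <- c("noun", "verb", "noun")
      script <- list(
        list(commands = list(cmdRecruit("N"))),
        list(commands = list(cmdRecruit("V"), cmdRecruit("S"),
                             cmdOpen("N", "n"), cmdOpen("S", "n"),
                             cmdOpen("V", "v"), cmdOpen("S", "v"),
                             cmdClose("N", "n"), cmdClose("S", "n"),
                             cmdClose("V", "v"), cmdClose("S", "v"),
                             cmdQuench("N"), cmdQuench("S", "main"))),
        list(commands = list(cmdRecruit("N"),
                             cmdOpen("V", "t"), cmdOpen("N", "t"),
                             cmdClose("V", "t"), cmdClose("N", "t"),
                             cmdQuench("V"), cmdQuench("N"))))
      ref <- .refGraph(tokens, cats, c("N1", "V1", "N2"),
                       rbind(.edge("S1", "n", "N1"), .edge("S1", "v", "V1"),
                             .edge("V1", "t", "N2")))
      list(tokens = tokens, cats = cats, script = script, ref = ref)
    },
    "bill-gates" = {
      tokens <- c("Bill-Gates", "has", "met", "two", "very", "tired",
                  "dancers", "in", "Dallas")
      cats <- c("noun", "aux", "verb", "num", "adv", "adj", "noun",
                "preposition", "noun")
      script <- list(
        list(commands = list(cmdRecruit("N"))),
        list(commands = list(cmdRecruit("Aux"), cmdRecruit("S"),
                             cmdOpen("N", "n"), cmdOpen("S", "n"),
                             cmdClose("N", "n"), cmdClose("S", "n"),
                             cmdQuench("N"))),
        list(commands = list(cmdRecruit("V"),
                             cmdOpen("V", "va"), cmdOpen("Aux", "va"),
                             cmdOpen("V", "v"), cmdOpen("S", "v"),
                             cmdClose("V", "va"), cmdClose("Aux", "va"),
                             cmdClose("V", "v"), cmdClose("S", "v"),
                             cmdQuench("Aux"), cmdQuench("S", "main"))),
        list(commands = list(cmdRecruit("Num"))),
        list(commands = list(cmdRecruit("Adv"),
                             cmdQuench("V", "concept"),
                             cmdQuench("Num", "concept"))),
        list(commands = list(cmdRecruit("Adj"),
                             cmdOpen("Adj", "ad"), cmdOpen("Adv", "ad"),
                             cmdClose("Adj", "ad"), cmdClose("Adv", "ad"),
                             cmdQuench("Adv"))),
        list(commands = list(cmdRecruit("N"),
                             cmdOpen("V", "t"), cmdOpen("N", "t"),
                             cmdOpen("N", "nm"), cmdOpen("Num", "nm"),
                             cmdOpen("N", "na"), cmdOpen("Adj", "na"),
                             cmdClose("V", "t"), cmdClose("N", "t"),
                             cmdClose("N", "nm"), cmdClose("Num", "nm"),
                             cmdClose("N", "na"), cmdClose("Adj", "na"),
                             cmdQuench("N"), cmdQuench("Num", "main"),
                             cmdQuench("Adj"))),
        list(commands = list(cmdRecruit("PP"),
                             cmdOpen("V", "pv"), cmdOpen("PP", "pv"),
                             cmdClose("V", "pv"), cmdClose("PP", "pv"),
                             cmdQuench("V", "main"))),
        list(commands = list(cmdRecruit("N"),
                             cmdOpen("PP", "pn"), cmdOpen("N", "pn"),
                             cmdClose("PP", "pn"), cmdClose("N", "pn"),
                             cmdQuench("PP"), cmdQuench("N"))))
      ref <- .refGraph(
        tokens, cats,
        c("N1", "Aux1", "V1", "Num1", "Adv1", "Adj1", "N2", "PP1", "N3"),
        rbind(.edge("S1", "n", "N1"), .edge("S1", "v", "V1"),
              .edge("V1", "va", "Aux1"), .edge("V1", "t", "N2"),
              .edge("N2", "nm", "Num1"), .edge("N2", "na", "Adj1"),
              .edge("Adj1", "ad", "Adv1"), .edge("V1", "pv", "PP1"),
              .edge("PP1", "pn", "N3")))
      list(tokens = tokens, cats = cats, script = script, ref = ref)
    },
    stop("unknown fixture: ", name, call. = FALSE))
}

#' Sentence fixtures
#'
#' Returns the named fixture: its tokens, category lexicon (including the
#' wh-words used in questions about it), parse script, reference binding
#' graph, a hand-specified flat chunk hierarchy and the default role map.
#'
#' @param name one of `"cat-is-on-mat"`, `"cat-sees-cat"`, `"bill-gates"`.
#' @return a list with elements `name`, `tokens`, `lexicon`, `vocabulary`,
#'   `script`, `referenceGraph`, `chunking`, `roleMap`.
#' @export
sentenceFixture <- function(name) {
  d <- .fixtureData(name)
  vocab <- stats::setNames(d$cats, d$tokens)
  vocab <- vocab[!duplicated(names(vocab))]
  lex <- c(vocab, c(where = "where", who = "who"))
  ## a repeated word re-uses its single in-situ assembly but needs a
  ## structure assembly per occurrence, so pools follow token counts
  kinds <- .bbCategoryKind[d$cats]
  pools <- table(kinds)
  pools <- stats::setNames(as.integer(pools), names(pools))
  pools["S"] <- 1L
  list(name = name, tokens = d$tokens, lexicon = lex, vocabulary = vocab,
       poolSizes = pools,
       script = d$script, referenceGraph = d$ref,
       chunking = .flatChunking(d$tokens, d$cats),
       roleMap = defaultRoleMap())
}

#' @rdname sentenceFixture
#' @export
fixtureNames <- function() .fixtureNames

#' Reservoir pre-trained on the fixture constructions
#'
#' Exactly the constructions needed for the three fixture sentences and
#' the wh-queries over them; any other category sequence is a parse error.
#'
#' @return a trained [Reservoir-class].
#' @export
defaultReservoir <- function() {
  res <- Reservoir()
  ex <- lapply(.fixtureNames, function(nm) {
    d <- .fixtureData(nm)
    list(key = d$cats, type = "parse", value = d$script)
  })
  ex <- c(ex, list(
    list(key = c("where", "localizer", "noun", "Agent"), type = "query",
         value = list(cue = "lastNoun", rolePath = c("n", "v", "pv", "pn"))),
    list(key = c("who", "verb", "noun", "Agent"), type = "query",
         value = list(cue = "verb", rolePath = c("v", "n"))),
    list(key = c("who", "verb", "noun", "Theme"), type = "query",
         value = list(cue = "verb", rolePath = c("v", "n")))))
  trainReadout(res, ex)
  res
}

## Run code under a seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate an artificial-language corpus with known word boundaries
#'
#' Concatenates words drawn i.i.d. from the lexicon (transitions inside a
#' word are deterministic; transitions between words follow the selection
#' distribution), so that boundary entropy is provably higher at word ends
#' than inside words.  Ground-truth boundaries are emitted alongside the
#' stream.
#'
#' @param lexicon list of words, each a character vector of symbols; the
#'   default is three trisyllabic words over nine distinct syllables.
#' @param probs word-selection probabilities (default uniform).
#' @param nTokens number of symbols to emit (complete words only).
#' @param seed RNG seed (required for reproducibility).
#' @param viewpoint viewpoint name carried by the emitted events.
#' @return list with `tokens` (character vector), `boundaries` (positions
#'   t such that a word ends at t), `events` (JSON-Lines-ready event
#'   list) and `wordIndex` (which lexicon word produced each token).
#' @export
genArtificialLanguage <- function(lexicon = list(c("ba", "di", "gu"),
                                                 c("tu", "pi", "ro"),
                                                 c("go", "la", "bu")),
                                  probs = NULL, nTokens = 900, seed = 7,
                                  viewpoint = "syll") {
  if (!length(lexicon)) stop("empty lexicon", call. = FALSE)
  if (any(vapply(lexicon, length, integer(1)) == 0L))
    stop("lexicon words must be non-empty", call. = FALSE)
  if (is.null(probs)) probs <- rep(1 / length(lexicon), length(lexicon))
  tokens <- character(0); bounds <- integer(0); widx <- integer(0)
  .withSeed(seed, {
    while (length(tokens) < nTokens) {
      w <- sample.int(length(lexicon), 1L, prob = probs)
      if (length(tokens) + length(lexicon[[w]]) > nTokens) break
      tokens <- c(tokens, lexicon[[w]])
      widx <- c(widx, rep(w, length(lexicon[[w]])))
      bounds <- c(bounds, length(tokens))
    }
  })
  events <- lapply(seq_along(tokens), function(i) {
    ev <- list(t = i)
    ev$vp <- stats::setNames(list(tokens[i]), viewpoint)
    ev
  })
  list(tokens = tokens, boundaries = bounds, events = events,
       wordIndex = widx)
}

#' Multi-viewpoint corpus for "John loves Mary"
#'
#' Phoneme-level event stream for the sentence, with synthetic smooth
#' pitch and amplitude contours (they exist to exercise continuous
#' viewpoint symbolisation, not to model speech) and a semantic-tag
#' viewpoint aligned with the words; the phoneme and semantic viewpoints
#' are the designated pair for a linked viewpoint.
#'
#' @param seed RNG seed for the contour jitter.
#' @return list with `events` (each carrying the four basic viewpoints
#'   `phoneme`, `pitch`, `amplitude`, `sem`) and `linked`, the viewpoint
#'   pair to link during learning.
#' @export
genJLM <- function(seed = 7) {
  phon <- c("dZ", "Q", "n", "l", "V", "v", "z", "m", "E@", "r", "i")
  sem <- c(rep("JOHN", 3), rep("LOVE", 4), rep("MARY", 4))
  vowel <- phon %in% c("Q", "V", "E@", "i")
  n <- length(phon)
  .withSeed(seed, {
    pitch <- 220 - 3.5 * seq_len(n) +
      8 * sin(2 * pi * seq_len(n) / n) + stats::rnorm(n, sd = 0.5)
    amplitude <- ifelse(vowel, 0.8, 0.45) +
      0.1 * sin(2 * pi * seq_len(n) / 4) + stats::rnorm(n, sd = 0.02)
  })
  events <- lapply(seq_len(n), function(i)
    list(t = i, vp = list(phoneme = phon[i], pitch = pitch[i],
                          amplitude = amplitude[i], sem = sem[i])))
  list(events = events, linked = c("phoneme", "sem"))
}

#' Read and write JSON-Lines event corpora
#'
#' One event per line, of the form
#' `{"t": 3, "vp": {"phoneme": "dZ", "sem": "JOHN"}}`.
#'
#' @param events list of events (`t`, `vp`).
#' @param path file path.
#' @return `path` (write) or the event list (read).
#' @export
writeCorpusJSONL <- function(events, path) {
  lines <- vapply(events, function(ev)
    as.character(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCorpusJSONL
#' @export
readCorpusJSONL <- function(path) {
  lapply(readLines(path), function(l) jsonlite::fromJSON(l))
}
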