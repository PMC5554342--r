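test_that("categorization is total on the fixture lexicons and errors otherwise", {
  lex <- sentenceFixture("cat-is-on-mat")$lexicon
  expect_equal(categorize("is", lex), "localizer")
  expect_equal(categorize("cat", lex), "noun")
  expect_error(categorize("", lex), "empty")
  expect_error(categorize("zebra", lex), "not in lexicon")
})

test_that("each fixture parse reproduces its reference graph", {
  for (nm in fixtureNames()) {
    fx <- sentenceFixture(nm)
    bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
    res <- parseSentence(fx$tokens, fx$lexicon, bb)
    v <- verifyIsomorphism(res$graph, fx$referenceGraph)
    expect_true(v$isomorphic, info = paste(nm, v$report))
  }
})

test_that("the problem of two: one cat assembly, two structure bindings", {
  fx <- sentenceFixture("cat-sees-cat")
  bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  g <- parseSentence(fx$tokens, fx$lexicon, bb)$graph
  catVerts <- g@vertices[g@vertices$type == "word" &
                           g@vertices$label == "cat", ]
  expect_equal(nrow(catVerts), 1L)
  wordEdges <- g@edges[g@edges$role == "word" & g@edges$a == "cat", ]
  expect_equal(sort(wordEdges$b), c("N1", "N2"))

  # subject vs theme retrieval distinguish the two occurrences: walk the
  # bound structure as an oracle for which N fills which slot
  el <- g@edges
  subjectN <- el$b[el$role == "n"]
  themeN <- el$b[el$role == "t"]
  expect_equal(subjectN, "N1")
  expect_equal(themeN, "N2")
  expect_equal(retrieveWords(bb, "sees", c("v", "n")), "cat")
  expect_equal(retrieveWords(bb, "sees", c("t")), "cat")
})

test_that("retrieval walks the bound path and respects the cue", {
  fx <- sentenceFixture("cat-is-on-mat")
  bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  parseSentence(fx$tokens, fx$lexicon, bb)
  expect_equal(retrieveWords(bb, "cat", c("n", "v", "pv", "pn")), "mat")
  expect_error(retrieveWords(bb, "zebra", "n"), "not in vocabulary")

  # empty blackboard: nothing beyond the cue
  bb2 <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  expect_length(retrieveWords(bb2, "cat", c("n", "v", "pv", "pn")), 0)
})

test_that("question recognition appends the blackboard role tag", {
  fx <- sentenceFixture("cat-is-on-mat")
  bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  parseSentence(fx$tokens, fx$lexicon, bb)
  expect_equal(recognizeQuery(c("where", "is", "cat"), fx$lexicon, bb),
               c("where", "localizer", "noun", "Agent"))
  # the tag is read off the bound graph: mat is bound via pn
  expect_equal(recognizeQuery(c("where", "is", "mat"), fx$lexicon, bb),
               c("where", "localizer", "noun", "Location"))
  # empty blackboard: open-query error
  bb2 <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  expect_error(recognizeQuery(c("where", "is", "cat"), fx$lexicon, bb2),
               class = "conceptboard_openQuery")
})

test_that("questions are answered from the bound structure", {
  fx <- sentenceFixture("cat-is-on-mat")
  bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  parseSentence(fx$tokens, fx$lexicon, bb)
  expect_equal(answerQuestion(c("where", "is", "cat"), fx$lexicon, bb),
               "mat")
  # empty blackboard: no-answer signal
  bb2 <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  expect_error(answerQuestion(c("where", "is", "cat"), fx$lexicon, bb2),
               class = "conceptboard_noAnswer")

  fx2 <- sentenceFixture("cat-sees-cat")
  bb3 <- makeBlackboard(fx2$vocabulary, fx2$poolSizes)
  parseSentence(fx2$tokens, fx2$lexicon, bb3)
  expect_equal(answerQuestion(c("who", "sees", "cat"), fx2$lexicon, bb3),
               "cat")
})

test_that("category abstraction: same construction generalizes to new nouns", {
  fx <- sentenceFixture("cat-is-on-mat")
  vocab <- c(fx$vocabulary, dog = "noun", couch = "noun")
  lex <- c(fx$lexicon, dog = "noun", couch = "noun")
  bb <- makeBlackboard(vocab, c(N = 2L, V = 1L, PP = 1L, S = 1L))
  parseSentence(c("dog", "is", "on", "couch"), lex, bb)
  expect_equal(answerQuestion(c("where", "is", "dog"), lex, bb), "couch")
})

test_that("order sensitivity: permuted tokens never silently parse", {
  fx <- sentenceFixture("cat-is-on-mat")
  bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  expect_error(parseSentence(c("is", "cat", "on", "mat"), fx$lexicon, bb),
               "not covered")
  expect_error(parseSentence(c("cat", "on", "is", "mat"), fx$lexicon, bb),
               "not covered")
})

test_that("feedback dependence: rebinding a noun changes the query tag", {
  fx <- sentenceFixture("cat-is-on-mat")
  vocab <- fx$vocabulary
  bb <- makeBlackboard(vocab, c(N = 2L, V = 1L, PP = 1L, S = 1L))
  # mat as subject this time: "mat is on cat"
  parseSentence(c("mat", "is", "on", "cat"), fx$lexicon, bb)
  expect_equal(recognizeQuery(c("where", "is", "mat"), fx$lexicon, bb)[4],
               "Agent")
  expect_equal(recognizeQuery(c("where", "is", "cat"), fx$lexicon, bb)[4],
               "Location")
})

test_that("readout training is exact association", {
  res <- Reservoir()
  # empty readout rejects everything
  fx <- sentenceFixture("cat-is-on-mat")
  bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  expect_error(parseSentence(fx$tokens, fx$lexicon, bb, reservoir = res),
               "not covered")

  # memorization: one trained construction replays exactly
  trainReadout(res, list(list(key = c("noun", "verb", "noun"),
                              type = "parse",
                              value = sentenceFixture("cat-sees-cat")$script)))
  fx2 <- sentenceFixture("cat-sees-cat")
  bb2 <- makeBlackboard(fx2$vocabulary, fx2$poolSizes)
  g <- parseSentence(fx2$tokens, fx2$lexicon, bb2, reservoir = res)$graph
  expect_true(verifyIsomorphism(g, fx2$referenceGraph)$isomorphic)

  # contradictory examples are a training error
  expect_error(trainReadout(res, list(
    list(key = c("noun", "verb", "noun"), type = "parse",
         value = list("something else")))), "contradictory")
})

test_that("script execution validates commands and vocabulary", {
  fx <- sentenceFixture("cat-is-on-mat")
  bb <- makeBlackboard(fx$vocabulary, fx$poolSizes)
  expect_error(executeScript(bb, c("cat", "zebra"), list(
    list(commands = list()), list(commands = list()))), "vocabulary")
  expect_error(executeScript(bb, "cat", list(
    list(commands = list(cmdOpen("N", "zz"))))), "invalid role")
  expect_error(executeScript(bb, "cat", list(
    list(commands = list(list(cmd = "recruit", kind = "ZZ"))))),
    "unknown kind")
})
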