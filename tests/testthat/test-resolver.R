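# Tree used throughout: ((Aus alpha,Bus beta),(Cus gamma,(Dus delta,Eus epsilon)))

test_that("minimum-clade cores are MRCAs; hand-checked against the five-tip tree", {
  tr <- tree5()
  tip <- function(lab) which(tr$tip.label == lab)
  expect_identical(
    resolve_minimum(tr, c(tip("Dus delta"), tip("Eus epsilon")))$tips,
    c("Dus delta", "Eus epsilon"))
  expect_identical(
    resolve_minimum(tr, c(tip("Aus alpha"), tip("Dus delta")))$tips,
    sort(tr$tip.label))
  expect_identical(resolve_minimum(tr, match(tr$tip.label, tr$tip.label))$tips,
                   sort(tr$tip.label))
})

test_that("maximum-clade cores walk rootward to the largest clade excluding the externals", {
  tr <- tree5()
  tip <- function(lab) which(tr$tip.label == lab)
  # derived by enumerating all 9 clades: those containing D but not A are
  # {D}, {D,E}, {C,D,E}; the largest is {C,D,E}
  r <- resolve_maximum(tr, tip("Dus delta"), tip("Aus alpha"))
  expect_true(r$ok)
  expect_identical(r$extent$tips, c("Cus gamma", "Dus delta", "Eus epsilon"))

  # sister exclusion leaves the tip clade
  r2 <- resolve_maximum(tr, tip("Dus delta"), tip("Eus epsilon"))
  expect_identical(r2$extent$tips, "Dus delta")

  # external inside the internals' MRCA: failure as data
  r3 <- resolve_maximum(tr, c(tip("Cus gamma"), tip("Eus epsilon")),
                        tip("Dus delta"))
  expect_false(r3$ok)
  expect_identical(r3$code, "EXTERNAL_INSIDE_MINIMAL")

  # exclusion_mode "any": lacking at least one external suffices
  r4 <- resolve_maximum(tr, tip("Dus delta"),
                        c(tip("Eus epsilon"), tip("Aus alpha")),
                        exclusion_mode = "any")
  expect_identical(r4$extent$tips, c("Cus gamma", "Dus delta", "Eus epsilon"))
  r5 <- resolve_maximum(tr, tip("Dus delta"),
                        c(tip("Eus epsilon"), tip("Aus alpha")),
                        exclusion_mode = "all")
  expect_identical(r5$extent$tips, "Dus delta")
})

test_that("qualifying clauses void rather than shrink: the three-tip hadrosaurid example", {
  # Hadrosaurus inside the Saurolophus+Lambeosaurus node
  inside <- read_newick("((Saurolophus_osborni,Hadrosaurus_foulkii),Lambeosaurus_lambei);")
  m <- resolve_minimum(inside, match(c("Saurolophus osborni", "Lambeosaurus lambei"),
                                     inside$tip.label))
  q <- apply_qualifying(inside, m, match("Hadrosaurus foulkii", inside$tip.label))
  expect_false(q$ok)
  expect_identical(q$code, "QUALIFIER_VIOLATED")

  outside <- read_newick("(Hadrosaurus_foulkii,(Saurolophus_osborni,Lambeosaurus_lambei));")
  m2 <- resolve_minimum(outside, match(c("Saurolophus osborni", "Lambeosaurus lambei"),
                                       outside$tip.label))
  expect_identical(m2$tips, c("Lambeosaurus lambei", "Saurolophus osborni"))
  q2 <- apply_qualifying(outside, m2, match("Hadrosaurus foulkii", outside$tip.label))
  expect_true(q2$ok)

  # empty exclusion list is vacuously satisfied
  expect_true(apply_qualifying(outside, m2, integer(0))$ok)
})

test_that("context checks implement within/outside semantics including equality and unresolved contexts", {
  tr <- tree5()
  abde <- clade_extent(tr, mrca_node(tr, c("Dus delta", "Eus epsilon")))
  cde <- clade_extent(tr, mrca_node(tr, c("Cus gamma", "Dus delta")))
  ab <- clade_extent(tr, mrca_node(tr, c("Aus alpha", "Bus beta")))

  within1 <- context_constraint("within", "Gammadae")
  expect_true(check_context(tr, abde, within1, list(Gammadae = cde))$ok)
  # subclade-or-equal includes equality
  expect_true(check_context(tr, cde, within1, list(Gammadae = cde))$ok)
  r <- check_context(tr, ab, within1, list(Gammadae = cde))
  expect_identical(r$code, "CONTEXT_VIOLATED")

  # within with "or": at least one; with "and": every one
  two_or <- context_constraint("within", c("Gammadae", "Alphadae"), "or")
  two_and <- context_constraint("within", c("Gammadae", "Alphadae"), "and")
  exts <- list(Gammadae = cde, Alphadae = ab)
  expect_true(check_context(tr, abde, two_or, exts)$ok)
  expect_identical(check_context(tr, abde, two_and, exts)$code,
                   "CONTEXT_VIOLATED")

  # outside: subclade of none, regardless of connective
  out_or <- context_constraint("outside", c("Gammadae", "Alphadae"), "or")
  expect_identical(check_context(tr, abde, out_or, exts)$code,
                   "CONTEXT_VIOLATED")  # nested in the first listed context
  expect_identical(check_context(tr, ab, out_or, exts)$code,
                   "CONTEXT_VIOLATED")  # nested in the second listed context
  root_ext <- clade_extent(tr, mrca_node(tr, tr$tip.label))
  expect_true(check_context(tr, root_ext, out_or, exts)$ok)

  # a failed context yields CONTEXT_UNRESOLVED when the check is undecidable
  fail <- list(ok = FALSE, code = "CONTEXT_VIOLATED", message = "x")
  expect_identical(
    check_context(tr, ab, within1, list(Gammadae = fail))$code,
    "CONTEXT_UNRESOLVED")
  # ...but a decidable outcome wins over an unresolved second context
  expect_true(check_context(tr, abde, two_or,
                            list(Gammadae = cde, Alphadae = fail))$ok)
  expect_error(check_context(tr, ab, within1, list()), "no context extent")
})

test_that("resolve_name runs the full pipeline with memoized context resolution and cycle detection", {
  tr <- tree5()
  corpus <- toy_corpus(
    Deltadae = list(abbr = "max ∇ (Dus delta ~ Aus alpha)"),
    Innerdae = list(abbr = "min ∇ ∈ Deltadae (Dus delta & Eus epsilon)"),
    Broaddae = list(abbr = "min ∇ ∈ Deltadae (Aus alpha & Dus delta)"),
    Ghostdae = list(abbr = "min ∇ (Dus delta & Zus zeta)"),
    Dropdae  = list(abbr = "max ∇ (Dus delta ~ Zus zeta & Aus alpha)"))

  r <- resolve_name(tr, corpus, "Innerdae")
  expect_identical(r$status, "resolved")
  expect_identical(extent_tips(r), c("Dus delta", "Eus epsilon"))

  r2 <- resolve_name(tr, corpus, "Broaddae")
  expect_identical(r2$status, "inapplicable")
  expect_identical(r2$reason_code, "CONTEXT_VIOLATED")

  # a missing internal specifier is unresolvable, distinct from inapplicable
  r3 <- resolve_name(tr, corpus, "Ghostdae")
  expect_identical(r3$status, "unresolvable")
  expect_identical(r3$reason_code, "MISSING_INTERNAL")
  expect_match(r3$reason, "Zus zeta")

  # unmatched externals are dropped with a warning, not fatal
  r4 <- resolve_name(tr, corpus, "Dropdae")
  expect_identical(r4$status, "resolved")
  expect_match(r4$warnings, "Zus zeta")
  expect_identical(extent_tips(r4), c("Cus gamma", "Dus delta", "Eus epsilon"))

  expect_error(resolve_name(tr, corpus, "Nosuchdae"), "unknown clade name")

  # resolve_all: corpus order, shared memoization (each core computed once)
  all_res <- resolve_all(tr, corpus)
  expect_identical(names(all_res), names(corpus))
  expect_identical(attr(all_res, "n_resolved"), length(corpus))
  expect_true(results_agree(all_res$Innerdae, r))

  # mutually referencing contexts: both names report a dependency cycle
  cyc <- toy_corpus(
    Aaa = list(abbr = "min ∇ ∈ Bbb (Dus delta & Eus epsilon)"),
    Bbb = list(abbr = "min ∇ ∈ Aaa (Cus gamma & Dus delta)"))
  rc <- resolve_all(tr, cyc)
  expect_identical(rc$Aaa$reason_code, "DEPENDENCY_CYCLE")
  expect_identical(rc$Bbb$reason_code, "DEPENDENCY_CYCLE")

  # a context name absent from the corpus is unresolved
  lone <- toy_corpus(Xxx = list(abbr = "min ∇ ∈ Nowheredae (Dus delta & Eus epsilon)"))
  expect_identical(resolve_name(tr, lone, "Xxx")$reason_code,
                   "CONTEXT_UNRESOLVED")
})

test_that("synonym detection reports all unordered equal-extent pairs with best-effort years", {
  tr <- tree5()
  corpus <- toy_corpus(
    One = list(abbr = "min ∇ (Dus delta & Eus epsilon)", authorship = "Marsh, 1890"),
    Two = list(abbr = "max ∇ (Dus delta ~ Cus gamma)", authorship = "Brown (1914)"),
    Three = list(abbr = "max ∇ (Eus epsilon ~ Cus gamma)", authorship = "Anonymous"),
    Apart = list(abbr = "min ∇ (Aus alpha & Bus beta)"))
  res <- resolve_all(tr, corpus)
  # One, Two, Three all resolve to the {D,E} cherry: three unordered pairs
  rep <- detect_synonyms(res, corpus)
  expect_identical(nrow(rep), 3L)
  expect_identical(sort(paste(rep$name_a, rep$name_b)),
                   c("One Three", "One Two", "Three Two"))
  expect_identical(rep$year_a[rep$name_a == "One"], c(1890L, 1890L))
  expect_true(all(is.na(rep$year_b[rep$name_b == "Three"])))
  expect_true(all(rep$extent == "Dus delta;Eus epsilon"))

  # no equal extents: empty report
  disjoint <- toy_corpus(
    P = list(abbr = "min ∇ (Aus alpha & Bus beta)"),
    Q = list(abbr = "min ∇ (Dus delta & Eus epsilon)"))
  expect_identical(nrow(detect_synonyms(resolve_all(tr, disjoint), disjoint)), 0L)
})

test_that("resolver and brute-force oracle agree on random trees under both exclusion modes", {
  for (i in 1:150) {
    tr <- binomial_tips(random_tree(sample(4:16, 1), seed = 2000 + i,
                                    polytomy_prob = 0.3))
    d <- random_definition(tr$tip.label, seed = 7000 + i)
    d$clade_name <- "Q"
    for (mode in c("all", "any")) {
      opts <- resolve_options(exclusion_mode = mode)
      a <- resolve_name(tr, list(d), "Q", opts)
      b <- brute_force_resolve(tr, d, options = opts)
      expect_true(results_agree(a, b),
                  label = sprintf("case %d mode %s", i, mode))
    }
  }
  expect_error(brute_force_resolve(random_tree(65, seed = 1),
                                   parse_definition("min ∇ (T1 a & T2 b)")),
               "64 tips")
})

test_that("adding an external specifier never enlarges a maximum clade", {
  for (i in 1:40) {
    tr <- binomial_tips(random_tree(sample(5:15, 1), seed = 4000 + i,
                                    polytomy_prob = 0.3))
    labs <- sample(tr$tip.label)
    internal <- labs[1]; e1 <- labs[2]; e2 <- labs[3]
    tipof <- function(l) match(l, tr$tip.label)
    r1 <- resolve_maximum(tr, tipof(internal), tipof(e1))
    r2 <- resolve_maximum(tr, tipof(internal), c(tipof(e1), tipof(e2)))
    if (r1$ok && r2$ok)
      expect_true(all(r2$extent$tips %in% r1$extent$tips))
    if (!r1$ok) expect_false(r2$ok)
  }
})

test_that("node-branch triplets partition the node into its two branches on binary trees", {
  # explicit hand-checked case on the five-tip tree
  tr <- tree5()
  tipof <- function(l) match(l, tr$tip.label)
  node <- resolve_minimum(tr, c(tipof("Aus alpha"), tipof("Cus gamma")))
  br1 <- resolve_maximum(tr, tipof("Aus alpha"), tipof("Cus gamma"))$extent
  br2 <- resolve_maximum(tr, tipof("Cus gamma"), tipof("Aus alpha"))$extent
  expect_identical(sort(c(br1$tips, br2$tips)), node$tips)
  expect_length(intersect(br1$tips, br2$tips), 0)

  for (i in 1:40) {
    tr <- binomial_tips(random_tree(sample(4:15, 1), seed = 5000 + i))
    labs <- sample(tr$tip.label, 2)
    tipof <- function(l) match(l, tr$tip.label)
    node <- resolve_minimum(tr, tipof(labs))
    b1 <- resolve_maximum(tr, tipof(labs[1]), tipof(labs[2]))
    b2 <- resolve_maximum(tr, tipof(labs[2]), tipof(labs[1]))
    expect_true(b1$ok && b2$ok)
    expect_identical(sort(c(b1$extent$tips, b2$extent$tips)), node$tips)
    expect_length(intersect(b1$extent$tips, b2$extent$tips), 0)
  }
})
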