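test_that("trivial maximum-clade definitions parse, with authorities captured and excluded from identity", {
  d <- parse_definition(
    "max ∇ (*Ankylosaurus magniventris* (Brown, 1908) ~ *Stegosaurus stenops* (Marsh, 1887))")
  expect_identical(d$kind, "maximum")
  expect_identical(taxon_binomials <- vapply(d$internal, `[[`, "", "binomial"),
                   "Ankylosaurus magniventris")
  expect_identical(vapply(d$external, `[[`, "", "binomial"),
                   "Stegosaurus stenops")
  expect_identical(d$internal[[1]]$authority, "(Brown, 1908)")
  expect_identical(d$external_connective, "none")
  # authority does not affect identity: same definition without authorities
  d2 <- parse_definition("max ∇ (Ankylosaurus magniventris ~ Stegosaurus stenops)")
  expect_identical(serialize_definition(d), serialize_definition(d2))

  # interposed authority words before a bracketed citation
  d3 <- parse_definition("max ∇ (Polacanthus foxii Owen in [Anon 1850] ~ Nodosaurus textilis)")
  expect_identical(d3$internal[[1]]$binomial, "Polacanthus foxii")
  expect_identical(d3$internal[[1]]$authority, "Owen in [Anon 1850]")
})

test_that("qualifying clauses and their connectives are recorded as printed", {
  d <- parse_definition(
    "min ∇ (Macrogryphosaurus gondwanicus & Talenkauen santacrucensis | ~ Hypsilophodon foxii ∨ Iguanodon bernissartensis ∨ Thescelosaurus neglectus)")
  expect_identical(d$kind, "minimum")
  expect_length(d$internal, 2)
  expect_length(d$external, 0)
  expect_length(d$qualifying_excluded, 3)
  expect_identical(d$qualifying_connective, "or")

  # a maximum-clade definition can carry both externals and a qualifier
  d2 <- parse_definition(
    "max ∇ (Saurolophus osborni ~ Lambeosaurus lambei | ~ Hadrosaurus foulkii)")
  expect_length(d2$external, 1)
  expect_identical(vapply(d2$qualifying_excluded, `[[`, "", "binomial"),
                   "Hadrosaurus foulkii")

  # no qualifying clause: serialization contains no bar token
  expect_false(grepl("|", serialize_definition(
    parse_definition("min ∇ (Aus alpha & Bus beta)")), fixed = TRUE))
})

test_that("context constraints parse with both polarities and connectives", {
  d1 <- parse_definition("min ∇ ∈ Ornithopoda (Edmontosaurus regalis & Hypsilophodon foxii)")
  expect_identical(d1$context$polarity, "within")
  expect_identical(d1$context$contexts, "Ornithopoda")
  expect_identical(d1$context$connective, "none")

  d2 <- parse_definition(
    "max ∇ ∉ Hypsilophodontidae ∨ Thescelosauridae (Jeholosaurus shangyuanensis ~ Hypsilophodon foxii & Thescelosaurus neglectus)")
  expect_identical(d2$context$polarity, "outside")
  expect_identical(d2$context$contexts,
                   c("Hypsilophodontidae", "Thescelosauridae"))
  expect_identical(d2$context$connective, "or")

  d3 <- parse_definition("max ∇ ∉ Lambeosaurini & Parasaurolophini (Aus alpha ~ Bus beta)")
  expect_identical(d3$context$connective, "and")
})

test_that("ASCII aliases and glyphs produce identical structures", {
  cases <- list(
    c("max ∇ (Ankylosaurus magniventris ~ Stegosaurus stenops)",
      "max-clade (Ankylosaurus magniventris not Stegosaurus stenops)"),
    c("min ∇ (Aus alpha & Bus beta | ~ Cus gamma)",
      "min-clade (Aus alpha and Bus beta provided-not Cus gamma)"),
    c("min ∇ ∈ Ornithopoda (Aus alpha & Bus beta)",
      "min-clade in Ornithopoda (Aus alpha and Bus beta)"),
    c("max ∇ ∉ Alphadae ∨ Betadae (Aus alpha ~ Bus beta ∨ Cus gamma)",
      "max-clade not-in Alphadae or Betadae (Aus alpha not Bus beta or Cus gamma)"))
  for (pair in cases) {
    expect_identical(
      serialize_definition(parse_definition(pair[1])),
      serialize_definition(parse_definition(pair[2])))
    expect_identical(serialize_definition(parse_definition(pair[1])), pair[1])
  }
})

test_that("malformed input raises positioned syntax errors; violated invariants raise validation errors", {
  expect_error(parse_definition("min ∇ (Aus alpha & Aus alpha)"),
               "duplicate specifier", class = "cladedef_validation_error")
  expect_error(parse_definition("min ∇ (Aus alpha)"),
               "requires >=2 internal", class = "cladedef_validation_error")
  expect_error(parse_definition("max ∇ (Aus alpha ~ Aus alpha)"),
               "both lists", class = "cladedef_validation_error")
  expect_error(parse_definition("min ∇ (Aus alpha & "),
               "position", class = "cladedef_syntax_error")
  expect_error(parse_definition("min ∇ (Aus alpha & Bus beta) extra"),
               "trailing", class = "cladedef_syntax_error")
  expect_error(parse_definition("blah ∇ (Aus alpha & Bus beta)"),
               "expected 'max' or 'min'", class = "cladedef_syntax_error")
  expect_error(parse_definition("max ∇ (Aus alpha ~ Bus beta & Cus gamma ∨ Dus delta)"),
               "mixed", class = "cladedef_syntax_error")
  # internal specifiers may only be joined by '&'
  expect_error(parse_definition("min ∇ (Aus alpha ∨ Bus beta)"),
               "unexpected", class = "cladedef_syntax_error")
})

test_that("validate_definition reports violations as data, not exceptions", {
  d <- parse_definition("max ∇ (Aus alpha ~ Bus beta)")
  expect_identical(validate_definition(d), character(0))

  d_broken <- d
  d_broken$external <- list()
  d_broken$external_connective <- "none"
  v <- validate_definition(d_broken)
  expect_length(v, 1)
  expect_match(v, "external.*requires >=1")

  d_conn <- d
  d_conn$external_connective <- "and"   # one member must carry "none"
  expect_match(validate_definition(d_conn), "connective")

  d_reg <- d
  d_reg$registration_number <- -5L
  expect_match(validate_definition(d_reg), "registration_number")
})

test_that("serialization round-trips: parse of serialize equals the original structure", {
  strings <- c(
    "min ∇ (Camptosaurus dispar & Iguanodon bernissartensis)",
    "max ∇ (Aralosaurus tuberiferus & Canardia garonnensis ~ Lambeosaurus lambei & Parasaurolophus walkeri & Tsintaosaurus spinorhinus)",
    "min ∇ ∈ Ornithopoda (Hypsilophodon foxii & Tenontosaurus tilletti | ~ Iguanodon bernissartensis)",
    "max ∇ ∈ Hypsilophodontidae ∨ Thescelosauridae (Orodromeus makelai ~ Hypsilophodon foxii & Thescelosaurus neglectus)")
  for (s in strings) {
    d <- parse_definition(s)
    expect_identical(serialize_definition(d), s)
    d2 <- parse_definition(serialize_definition(d))
    expect_identical(serialize_definition(d2), s)
  }
})
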