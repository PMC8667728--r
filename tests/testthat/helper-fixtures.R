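# Shared fixtures, all built in code.

# five-tip binary tree with binomial labels; extents are easy to hand-check
tree5 <- function()
  read_newick("((Aus_alpha,Bus_beta),(Cus_gamma,(Dus_delta,Eus_epsilon)));")

# relabel random_tree tips T1..Tn to binomials usable as specifiers
binomial_tips <- function(phy) {
  phy$tip.label <- sub("^T", "Taxon t", phy$tip.label)
  phy
}

# minimal corpus from definitions given as abbreviated strings
toy_corpus <- function(...) {
  specs <- list(...)
  entries <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    parse_definition(s$abbr, clade_name = nm,
                     registration_number = s$reg %||% NA_integer_,
                     authorship = s$authorship %||% NA_character_,
                     status = s$status %||% NA_character_)
  })
  names(entries) <- names(specs)
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extent_tips <- function(result) {
  if (is.null(result$extent)) NULL else result$extent$tips
}

# multiset of clade extents as a sorted character vector of keys
extent_multiset <- function(phy) {
  sort(vapply(enumerate_clades(phy),
              function(cl) paste(cl$tips, collapse = ";"), character(1)))
}

results_agree <- function(a, b) {
  identical(a$status, b$status) &&
    identical(a$reason_code, b$reason_code) &&
    identical(extent_tips(a), extent_tips(b))
}
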