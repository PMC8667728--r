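# Support for property testing: randomized definitions to pair with
# random_tree(). Kept in the package (rather than in the test helpers) so
# the oracle-equivalence experiment is reproducible from an installed
# package alone.

#' Generate a seeded random clade definition over a label set
#'
#' Draws a minimum- or maximum-clade definition anchored on the given tip
#' labels: 2-3 internal specifiers for minimum-kind, 1-3 internals plus
#' 1-3 disjoint externals for maximum-kind, and optionally 1-2
#' qualifying-clause exclusions. With probability `missing_prob` one
#' internal specifier is replaced by a binomial absent from the label set,
#' exercising the unresolvable path. Deterministic for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param labels character vector of candidate specifier names; must be
#'   species binomials (at least 4). [random_tree()] tips `T1..Tn` can be
#'   relabeled, e.g. to `"Taxon t1"`, before use.
#' @param seed integer seed (required).
#' @param missing_prob probability of planting an absent internal
#'   specifier.
#' @return a `"clade_definition"` (unnamed, no registration metadata).
#' @export
random_definition <- function(labels, seed, missing_prob = 0.1) {
  stopifnot(length(labels) >= 4)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  kind <- sample(c("minimum", "maximum"), 1)
  pool <- sample(labels)
  n_int <- if (kind == "minimum") sample(2:3, 1) else sample(1:3, 1)
  internal <- pool[seq_len(n_int)]; pool <- pool[-seq_len(n_int)]
  external <- character(0)
  if (kind == "maximum") {
    n_ext <- min(sample(1:3, 1), length(pool))
    external <- pool[seq_len(n_ext)]; pool <- pool[-seq_len(n_ext)]
  }
  qualifying <- character(0)
  if (length(pool) && stats::runif(1) < 0.5)
    qualifying <- pool[seq_len(min(sample(1:2, 1), length(pool)))]
  if (stats::runif(1) < missing_prob)
    internal[sample(length(internal), 1)] <- "Absentia phantasma"
  clade_definition(
    clade_name = NA_character_, kind = kind,
    internal = internal, external = external, qualifying = qualifying)
}
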