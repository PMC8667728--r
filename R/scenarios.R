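# Scenario trees: small synthetic topologies, each encoding a published
# placement hypothesis that changes how one or more clade names resolve.
# The trees are minimal toy encodings of verbally described placements,
# never traced from published figures; provenance fields paraphrase the
# hypothesis a scenario stands for. Expected outcomes are attached so the
# scenarios double as an executable regression suite.

scenario_expect <- function(clade_name, status, reason = NA_character_,
                            extent = NA_character_) {
  data.frame(clade_name = clade_name, status = status, reason = reason,
             extent = extent, stringsAsFactors = FALSE)
}

ext <- function(...) paste(sort(c(...)), collapse = ";")

SCENARIOS <- list(

  primary_hadrosaurid = list(
    description = "Reference hadrosaurid arrangement: Hadrosaurus foulkii is the sister taxon of the clade uniting saurolophines and lambeosaurines.",
    provenance = "The consensus hadrosaurid topology, under which Hadrosaurus foulkii falls outside the smallest clade containing Saurolophus osborni and Lambeosaurus lambei, so Saurolophinae and Euhadrosauria both apply.",
    newick = "(Iguanodon_bernissartensis,(Hadrosaurus_foulkii,((Brachylophosaurus_canadensis,(Kritosaurus_navajovius,(Edmontosaurus_regalis,Saurolophus_osborni))),((Aralosaurus_tuberiferus,Canardia_garonnensis),((Pararhabdodon_isonensis,Tsintaosaurus_spinorhinus),((Lambeosaurus_lambei,Corythosaurus_casuarius),Parasaurolophus_walkeri))))));",
    expected = rbind(
      scenario_expect("Hadrosauridae", "resolved", extent = ext(
        "Hadrosaurus foulkii", "Brachylophosaurus canadensis",
        "Kritosaurus navajovius", "Edmontosaurus regalis",
        "Saurolophus osborni", "Aralosaurus tuberiferus",
        "Canardia garonnensis", "Pararhabdodon isonensis",
        "Tsintaosaurus spinorhinus", "Lambeosaurus lambei",
        "Corythosaurus casuarius", "Parasaurolophus walkeri")),
      scenario_expect("Euhadrosauria", "resolved", extent = ext(
        "Brachylophosaurus canadensis", "Kritosaurus navajovius",
        "Edmontosaurus regalis", "Saurolophus osborni",
        "Aralosaurus tuberiferus", "Canardia garonnensis",
        "Pararhabdodon isonensis", "Tsintaosaurus spinorhinus",
        "Lambeosaurus lambei", "Corythosaurus casuarius",
        "Parasaurolophus walkeri")),
      scenario_expect("Saurolophinae", "resolved", extent = ext(
        "Brachylophosaurus canadensis", "Kritosaurus navajovius",
        "Edmontosaurus regalis", "Saurolophus osborni")),
      scenario_expect("Hadrosaurinae", "resolved",
                      extent = "Hadrosaurus foulkii"),
      scenario_expect("Aralosaurini", "resolved", extent = ext(
        "Aralosaurus tuberiferus", "Canardia garonnensis")),
      scenario_expect("Tsintaosaurini", "resolved", extent = ext(
        "Pararhabdodon isonensis", "Tsintaosaurus spinorhinus")),
      scenario_expect("Corythosauria", "resolved", extent = ext(
        "Lambeosaurus lambei", "Corythosaurus casuarius",
        "Parasaurolophus walkeri")),
      scenario_expect("Lambeosaurinae", "resolved", extent = ext(
        "Aralosaurus tuberiferus", "Canardia garonnensis",
        "Pararhabdodon isonensis", "Tsintaosaurus spinorhinus",
        "Lambeosaurus lambei", "Corythosaurus casuarius",
        "Parasaurolophus walkeri")))),

  hadrosaurus_inside = list(
    description = "Hadrosaurus foulkii nested inside the saurolophine branch of the saurolophine+lambeosaurine node.",
    provenance = "The alternative placement in which Hadrosaurus foulkii is reconstructed within the smallest clade containing Saurolophus osborni and Lambeosaurus lambei, on the Saurolophus side: Hadrosaurinae is then the applicable name for that branch while Saurolophinae and Euhadrosauria are voided by their qualifying clauses.",
    newick = "(Iguanodon_bernissartensis,((Brachylophosaurus_canadensis,(Kritosaurus_navajovius,(Edmontosaurus_regalis,(Hadrosaurus_foulkii,Saurolophus_osborni)))),((Aralosaurus_tuberiferus,Canardia_garonnensis),((Pararhabdodon_isonensis,Tsintaosaurus_spinorhinus),((Lambeosaurus_lambei,Corythosaurus_casuarius),Parasaurolophus_walkeri)))));",
    expected = rbind(
      scenario_expect("Euhadrosauria", "inapplicable", "QUALIFIER_VIOLATED"),
      scenario_expect("Saurolophinae", "inapplicable", "QUALIFIER_VIOLATED"),
      scenario_expect("Hadrosaurinae", "resolved", extent = ext(
        "Brachylophosaurus canadensis", "Kritosaurus navajovius",
        "Edmontosaurus regalis", "Hadrosaurus foulkii",
        "Saurolophus osborni")),
      scenario_expect("Hadrosauridae", "resolved", extent = ext(
        "Hadrosaurus foulkii", "Brachylophosaurus canadensis",
        "Kritosaurus navajovius", "Edmontosaurus regalis",
        "Saurolophus osborni", "Aralosaurus tuberiferus",
        "Canardia garonnensis", "Pararhabdodon isonensis",
        "Tsintaosaurus spinorhinus", "Lambeosaurus lambei",
        "Corythosaurus casuarius", "Parasaurolophus walkeri")))),

  heterodontosaurids_in_pachycephalosauria = list(
    description = "Heterodontosaurids as early-diverging pachycephalosaurs, with Echinodon and Tianyulong closer to pachycephalosaurids than to Heterodontosaurus.",
    provenance = "The hypothesis that recovers heterodontosaurids inside Pachycephalosauria and pulls Echinodon becklesii and Tianyulong confuciusi toward the pachycephalosaurids; the name Heterodontosauridae then still applies, to the clade of Abrictosaurus consors, Fruitadens haagarorum, Heterodontosaurus tucki, and Lycorhinus angustidens.",
    newick = "((Stegosaurus_stenops,Ankylosaurus_magniventris),(Iguanodon_bernissartensis,(((Abrictosaurus_consors,(Fruitadens_haagarorum,(Heterodontosaurus_tucki,Lycorhinus_angustidens))),((Echinodon_becklesii,Tianyulong_confuciusi),(Pachycephalosaurus_wyomingensis,Stegoceras_validum))),(Triceratops_horridus,Protoceratops_andrewsi))));",
    expected = rbind(
      scenario_expect("Heterodontosauridae", "resolved", extent = ext(
        "Abrictosaurus consors", "Fruitadens haagarorum",
        "Heterodontosaurus tucki", "Lycorhinus angustidens")))),

  leptoceratopsids_sister_to_ceratopsoidea = list(
    description = "Leptoceratopsids recovered as the sister taxon of Ceratopsoidea, with Protoceratopsidae one node below.",
    provenance = "The topology under which leptoceratopsids are the sister taxon to Ceratopsoidea and Protoceratopsidae is the sister taxon of that pair: the node anchored by Leptoceratops, Protoceratops, and Triceratops then coincides with the Protoceratops+Triceratops node, making the two names heterodefinitional synonyms on this tree.",
    newick = "(Psittacosaurus_mongoliensis,((Protoceratops_andrewsi,Bagaceratops_rozhdestvenskyi),((Leptoceratops_gracilis,Udanoceratops_tschizhovi),(Triceratops_horridus,(Centrosaurus_apertus,Ceratops_montanus)))));",
    expected = rbind(
      scenario_expect("Euceratopsia", "resolved", extent = ext(
        "Protoceratops andrewsi", "Bagaceratops rozhdestvenskyi",
        "Leptoceratops gracilis", "Udanoceratops tschizhovi",
        "Triceratops horridus", "Centrosaurus apertus",
        "Ceratops montanus")),
      scenario_expect("Coronosauria", "resolved", extent = ext(
        "Protoceratops andrewsi", "Bagaceratops rozhdestvenskyi",
        "Leptoceratops gracilis", "Udanoceratops tschizhovi",
        "Triceratops horridus", "Centrosaurus apertus",
        "Ceratops montanus")))),

  primary_ceratopsian = list(
    description = "Reference ceratopsian arrangement: protoceratopsids and ceratopsoids are sisters, leptoceratopsids one node below.",
    provenance = "The consensus arrangement in which Euceratopsia branches into leptoceratopsids and coronosaurs (protoceratopsids + ceratopsoids); Euceratopsia and Coronosauria then name different nodes.",
    newick = "(Psittacosaurus_mongoliensis,((Leptoceratops_gracilis,Udanoceratops_tschizhovi),((Protoceratops_andrewsi,Bagaceratops_rozhdestvenskyi),(Triceratops_horridus,(Centrosaurus_apertus,Ceratops_montanus)))));",
    expected = rbind(
      scenario_expect("Coronosauria", "resolved", extent = ext(
        "Protoceratops andrewsi", "Bagaceratops rozhdestvenskyi",
        "Triceratops horridus", "Centrosaurus apertus",
        "Ceratops montanus")),
      scenario_expect("Euceratopsia", "resolved", extent = ext(
        "Leptoceratops gracilis", "Udanoceratops tschizhovi",
        "Protoceratops andrewsi", "Bagaceratops rozhdestvenskyi",
        "Triceratops horridus", "Centrosaurus apertus",
        "Ceratops montanus")))),

  aralosaurus_separated = list(
    description = "Aralosaurus closer to Lambeosaurus than to Canardia, splitting the Aralosaurini internal specifiers apart.",
    provenance = "A subset of recent lambeosaurine topologies separates Aralosaurus tuberiferus from Canardia garonnensis, so the smallest clade containing both also contains the external specifiers and Aralosaurini is inapplicable.",
    newick = "(Hadrosaurus_foulkii,((Canardia_garonnensis,(Pararhabdodon_isonensis,Tsintaosaurus_spinorhinus)),(Aralosaurus_tuberiferus,((Lambeosaurus_lambei,Corythosaurus_casuarius),Parasaurolophus_walkeri))));",
    expected = rbind(
      scenario_expect("Aralosaurini", "inapplicable",
                      "EXTERNAL_INSIDE_MINIMAL"))),

  tsintaosaurus_separated = list(
    description = "Tsintaosaurus drawn toward Lambeosaurini, away from Pararhabdodon.",
    provenance = "Topologies separating Pararhabdodon isonensis from Tsintaosaurus spinorhinus place external specifiers inside the smallest clade containing both, making Tsintaosaurini inapplicable.",
    newick = "(Hadrosaurus_foulkii,((Aralosaurus_tuberiferus,Canardia_garonnensis),((Pararhabdodon_isonensis,Parasaurolophus_walkeri),(Tsintaosaurus_spinorhinus,(Lambeosaurus_lambei,Corythosaurus_casuarius)))));",
    expected = rbind(
      scenario_expect("Tsintaosaurini", "inapplicable",
                      "EXTERNAL_INSIDE_MINIMAL"),
      scenario_expect("Aralosaurini", "resolved", extent = ext(
        "Aralosaurus tuberiferus", "Canardia garonnensis")))),

  hypsilophodon_outside_ornithopoda = list(
    description = "Hypsilophodon foxii and Heterodontosaurus tucki placed outside Ornithopoda, as early-diverging neornithischians.",
    provenance = "The unstable position of Hypsilophodon foxii among neornithischians: when it (and Heterodontosaurus tucki) falls outside Ornithopoda, the names restricted to apply within Ornithopoda -- Clypeodonta, Euornithopoda, and Hypsilophodontia -- become inapplicable.",
    newick = "((Stegosaurus_stenops,Ankylosaurus_magniventris),(Heterodontosaurus_tucki,(Hypsilophodon_foxii,((Pachycephalosaurus_wyomingensis,Triceratops_horridus),(Thescelosaurus_neglectus,(Tenontosaurus_tilletti,(Dryosaurus_altus,(Camptosaurus_dispar,(Iguanodon_bernissartensis,(Hadrosaurus_foulkii,Edmontosaurus_regalis))))))))));",
    expected = rbind(
      scenario_expect("Ornithopoda", "resolved", extent = ext(
        "Thescelosaurus neglectus", "Tenontosaurus tilletti",
        "Dryosaurus altus", "Camptosaurus dispar",
        "Iguanodon bernissartensis", "Hadrosaurus foulkii",
        "Edmontosaurus regalis")),
      scenario_expect("Clypeodonta", "inapplicable", "CONTEXT_VIOLATED"),
      scenario_expect("Euornithopoda", "inapplicable", "CONTEXT_VIOLATED"),
      scenario_expect("Hypsilophodontia", "inapplicable",
                      "QUALIFIER_VIOLATED"))),

  heterodontosaurids_basal_ornithopods = list(
    description = "The traditional arrangement with heterodontosaurids as the earliest-diverging ornithopods.",
    provenance = "The older view of heterodontosaurids as basal ornithopods: Heterodontosaurus tucki then lies inside Ornithopoda and Euornithopoda applies, naming the ornithopods exclusive of heterodontosaurids.",
    newick = "((Stegosaurus_stenops,Ankylosaurus_magniventris),((Pachycephalosaurus_wyomingensis,Triceratops_horridus),(Heterodontosaurus_tucki,(Hypsilophodon_foxii,(Tenontosaurus_tilletti,(Iguanodon_bernissartensis,Hadrosaurus_foulkii))))));",
    expected = rbind(
      scenario_expect("Ornithopoda", "resolved", extent = ext(
        "Heterodontosaurus tucki", "Hypsilophodon foxii",
        "Tenontosaurus tilletti", "Iguanodon bernissartensis",
        "Hadrosaurus foulkii")),
      scenario_expect("Euornithopoda", "resolved", extent = ext(
        "Hypsilophodon foxii", "Tenontosaurus tilletti",
        "Iguanodon bernissartensis", "Hadrosaurus foulkii")))),

  jeholosaurus_in_thescelosauridae = list(
    description = "Jeholosaurus nested inside Thescelosauridae, as sister to Orodromeus.",
    provenance = "The hypotheses that pull Jeholosaurus shangyuanensis into Thescelosauridae: the definition of Jeholosauridae applies outside Hypsilophodontidae or Thescelosauridae, so on such trees the name is inapplicable while Orodrominae still applies.",
    newick = "(Stegosaurus_stenops,(Hypsilophodon_foxii,((Pachycephalosaurus_wyomingensis,Triceratops_horridus),((Thescelosaurus_neglectus,(Orodromeus_makelai,Jeholosaurus_shangyuanensis)),(Tenontosaurus_tilletti,Iguanodon_bernissartensis)))));",
    expected = rbind(
      scenario_expect("Thescelosauridae", "resolved", extent = ext(
        "Thescelosaurus neglectus", "Orodromeus makelai",
        "Jeholosaurus shangyuanensis")),
      scenario_expect("Jeholosauridae", "inapplicable", "CONTEXT_VIOLATED"),
      scenario_expect("Orodrominae", "resolved", extent = ext(
        "Orodromeus makelai", "Jeholosaurus shangyuanensis"))))
)

#' List the packaged scenario trees
#'
#' @return data.frame with columns `id` and `description`.
#' @export
list_scenarios <- function() {
  data.frame(id = names(SCENARIOS),
             description = vapply(SCENARIOS, `[[`, character(1), "description"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a packaged scenario tree
#'
#' Each scenario is a deterministic fixture built from an in-code Newick
#' literal: a small topology encoding a placement hypothesis, a provenance
#' note stating which hypothesis, and the expected resolution outcomes of
#' the clade names the scenario exercises.
#'
#' @param id scenario identifier; see [list_scenarios()].
#' @return an object of class `"scenario_tree"`: a list with `id`,
#'   `description`, `provenance`, `newick`, `tree` (a `"phylo"`), and
#'   `expected` (a data.frame of `clade_name`, `status`, `reason`,
#'   `extent`).
#' @export
scenario_tree <- function(id) {
  if (!id %in% names(SCENARIOS))
    stop(sprintf("unknown scenario id '%s'; available: %s", id,
                 paste(names(SCENARIOS), collapse = ", ")), call. = FALSE)
  sc <- SCENARIOS[[id]]
  structure(list(id = id, description = sc$description,
                 provenance = sc$provenance, newick = sc$newick,
                 tree = read_newick(sc$newick), expected = sc$expected),
            class = "scenario_tree")
}

#' @export
print.scenario_tree <- function(x, ...) {
  cat(sprintf("scenario '%s' (%d tips)\n  %s\n", x$id,
              ape::Ntip(x$tree), x$description))
  invisible(x)
}

#' Check a scenario's expected outcomes
#'
#' Resolves every name listed in the scenario's expectation table against
#' the scenario tree and compares status, reason code, and extent.
#'
#' @param scenario a `"scenario_tree"` (or an id).
#' @param corpus corpus to resolve against (default: the packaged corpus).
#' @param options a [resolve_options()] list.
#' @return data.frame: the expectation table with observed columns and a
#'   logical `ok` per row.
#' @export
check_scenario <- function(scenario, corpus = load_corpus(),
                           options = resolve_options()) {
  if (is.character(scenario)) scenario <- scenario_tree(scenario)
  exp <- scenario$expected
  obs <- lapply(exp$clade_name, function(nm)
    resolve_name(scenario$tree, corpus, nm, options))
  exp$observed_status <- vapply(obs, `[[`, character(1), "status")
  exp$observed_reason <- vapply(obs, function(r)
    if (is.null(r$reason_code)) NA_character_ else r$reason_code, character(1))
  exp$observed_extent <- vapply(obs, function(r)
    if (is.null(r$extent)) NA_character_
    else paste(r$extent$tips, collapse = ";"), character(1))
  exp$ok <- exp$status == exp$observed_status &
    (is.na(exp$reason) | exp$reason == exp$observed_reason) &
    (is.na(exp$extent) | exp$extent == exp$observed_extent)
  exp
}
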