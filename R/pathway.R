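#' Load a pathway definition
#'
#' Reads a pathway definition (metabolites, reactions, pools) from a YAML or
#' JSON file and validates it. The package bundles a default definition of
#' Entner-Doudoroff glycolysis plus the seven-step MEP pathway of
#' *Zymomonas mobilis* (with the heterologous isoprene synthase step), which
#' [mep_pathway()] loads.
#'
#' Validation checks that ids are unique, every id referenced by a reaction
#' stoichiometry or a pool resolves to a metabolite, reactions are
#' carbon-balanced given the metabolite formulas, each reaction's main
#' substrate/product have the correct stoichiometric sign, combined-pool
#' partners (the IDP/DMADP case) reference each other symmetrically, and the
#' MEP main chain DXP -> ... -> IDP/DMADP forms a connected linear path.
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON file with top-level
#'   keys `metabolites`, `reactions` and `pools`.
#' @return A `pathway_map` object: a list with tibbles `metabolites` (columns
#'   `id`, `name`, `formula`, `n_carbon`, `category`,
#'   `measured_as_pool_with`) and `reactions` (columns `id`, `stoichiometry`
#'   list-column of named numeric vectors, `main_substrate`, `main_product`),
#'   and a named list `pools` of metabolite-id character vectors.
#' @examples
#' pw <- mep_pathway()
#' pw$reactions$id
#' pw$pools$MEP
#' @export
load_pathway <- function(path) {
  stopifnot(is.character(path), length(path) == 1, file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  mets <- purrr::map_dfr(raw$metabolites, function(m) {
    tibble::tibble(
      id = as.character(m$id),
      name = as.character(m$name %||% m$id),
      formula = as.character(m$formula),
      category = as.character(m$category %||% "other"),
      measured_as_pool_with = as.character(m$measured_as_pool_with %||% NA_character_)
    )
  })
  mets$n_carbon <- vapply(mets$formula, formula_carbons, numeric(1), USE.NAMES = FALSE)
  rxns <- purrr::map_dfr(raw$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    tibble::tibble(
      id = as.character(r$id),
      stoichiometry = list(stats::setNames(as.numeric(st), names(st))),
      main_substrate = as.character(r$main_substrate),
      main_product = as.character(r$main_product),
      dg0_prime = as.numeric(r$dg0_prime %||% NA_real_),
      dg0_se = as.numeric(r$dg0_se %||% NA_real_)
    )
  })
  pools <- purrr::map(raw$pools, ~ as.character(unlist(.x)))
  pw <- structure(
    list(metabolites = mets, reactions = rxns, pools = pools),
    class = "pathway_map"
  )
  validate_pathway(pw)
  pw
}

#' @rdname load_pathway
#' @export
mep_pathway <- function() {
  load_pathway(system.file("extdata", "mep_pathway.yaml", package = "mepscope",
                           mustWork = TRUE))
}

#' Validate a pathway map
#'
#' @param pw A `pathway_map` object (see [load_pathway()]).
#' @return `pw`, invisibly; errors describe the first violated constraint.
#' @export
validate_pathway <- function(pw) {
  stopifnot(inherits(pw, "pathway_map"))
  mets <- pw$metabolites
  rxns <- pw$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  ok_cat <- c("MEP", "ED_glycolysis", "NTP", "cofactor",
              "downstream_isoprenoid", "other")
  bad <- setdiff(unique(mets$category), ok_cat)
  if (length(bad)) stop("unknown metabolite category: ", paste(bad, collapse = ", "))

  nc <- stats::setNames(mets$n_carbon, mets$id)
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown)) {
      stop("reaction ", rxns$id[i], " references unknown metabolite id: ",
           paste(unknown, collapse = ", "))
    }
    cbal <- sum(st * nc[names(st)])
    if (abs(cbal) > 1e-9) {
      stop("reaction ", rxns$id[i], " is not carbon balanced (net C = ", cbal, ")")
    }
    if (is.na(st[rxns$main_substrate[i]]) || st[rxns$main_substrate[i]] >= 0) {
      stop("reaction ", rxns$id[i], ": main_substrate must be consumed (nu < 0)")
    }
    if (is.na(st[rxns$main_product[i]]) || st[rxns$main_product[i]] <= 0) {
      stop("reaction ", rxns$id[i], ": main_product must be produced (nu > 0)")
    }
  }
  for (p in names(pw$pools)) {
    unknown <- setdiff(pw$pools[[p]], mets$id)
    if (length(unknown)) {
      stop("pool ", p, " references unknown metabolite id: ",
           paste(unknown, collapse = ", "))
    }
  }
  # symmetric combined-pool partners
  has_partner <- !is.na(mets$measured_as_pool_with)
  for (i in which(has_partner)) {
    partner <- mets$measured_as_pool_with[i]
    j <- match(partner, mets$id)
    if (is.na(j)) stop("pool partner of ", mets$id[i], " not found: ", partner)
    if (is.na(mets$measured_as_pool_with[j]) ||
        mets$measured_as_pool_with[j] != mets$id[i]) {
      stop("pool partnership not symmetric: ", mets$id[i], " <-> ", partner)
    }
  }
  check_main_chain(pw)
  invisible(pw)
}

# The MEP main chain must be linear and connected: starting at DXP, following
# each reaction's main substrate -> main product must reach the IDP/DMADP pool.
check_main_chain <- function(pw) {
  rxns <- pw$reactions
  edges <- stats::setNames(rxns$main_product, rxns$main_substrate)
  node <- "DXP"
  if (!"DXP" %in% names(edges)) stop("broken MEP main chain: no reaction consumes DXP")
  seen <- character(0)
  while (node %in% names(edges) && node != "IDP/DMADP") {
    if (node %in% seen) stop("broken MEP main chain: cycle at ", node)
    seen <- c(seen, node)
    node <- unname(edges[node])
  }
  if (node != "IDP/DMADP") {
    stop("broken MEP main chain: path from DXP ends at ", node)
  }
  invisible(TRUE)
}

#' Write a pathway map back to YAML
#'
#' Inverse of [load_pathway()]: re-reading the written file reproduces an
#' identical object.
#'
#' @param pw A `pathway_map`.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_pathway <- function(pw, path) {
  stopifnot(inherits(pw, "pathway_map"))
  mets <- purrr::pmap(pw$metabolites, function(id, name, formula, category,
                                               measured_as_pool_with, n_carbon) {
    out <- list(id = id, name = name, formula = formula, category = category)
    if (!is.na(measured_as_pool_with)) out$measured_as_pool_with <- measured_as_pool_with
    out
  })
  rxns <- purrr::pmap(pw$reactions, function(id, stoichiometry, main_substrate,
                                             main_product, dg0_prime, dg0_se) {
    out <- list(id = id, stoichiometry = as.list(stoichiometry),
                main_substrate = main_substrate, main_product = main_product)
    if (!is.na(dg0_prime)) out$dg0_prime <- dg0_prime
    if (!is.na(dg0_se)) out$dg0_se <- dg0_se
    out
  })
  yaml::write_yaml(list(metabolites = mets, reactions = rxns, pools = pw$pools),
                   path)
  invisible(path)
}

#' @export
print.pathway_map <- function(x, ...) {
  cat("<pathway_map> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$pools), " pools\n", sep = "")
  cat("reactions: ", paste(x$reactions$id, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Carbon count from a Hill-notation formula string.
formula_carbons <- function(formula) {
  m <- regmatches(formula, regexec("C([0-9]*)([A-Z]|$)", formula))[[1]]
  if (length(m) == 0 || m[1] == "") return(0)
  # "C" alone means one carbon; "Cl"/"Ca" etc. are not in scope here
  if (m[2] == "") 1 else as.numeric(m[2])
}

#' Mass shift of the uniformly 13C-labeled isotopologue
#'
#' Growth on uniformly labeled \[U-13C\] glucose replaces every carbon with
#' 13C, shifting the monoisotopic mass by `n_carbon x (13.003355 - 12)` Da.
#' The shift is exactly linear in the carbon count.
#'
#' @param x A metabolite id (looked up in `pathway`), or directly an integer
#'   carbon count.
#' @param pathway A `pathway_map` used to resolve ids; defaults to the
#'   bundled MEP pathway.
#' @return Mass difference in Da.
#' @examples
#' isotope_mass_shift("DXP")  # 5 carbons -> 5.016775
#' isotope_mass_shift(3)      # pyruvate  -> 3.010065
#' @export
isotope_mass_shift <- function(x, pathway = mep_pathway()) {
  delta <- 13.003355 - 12.000000
  if (is.numeric(x)) {
    stopifnot(all(x >= 0))
    return(x * delta)
  }
  i <- match(x, pathway$metabolites$id)
  if (anyNA(i)) stop("unknown metabolite id: ", paste(x[is.na(i)], collapse = ", "))
  n <- pathway$metabolites$n_carbon[i]
  if (anyNA(n)) stop("unknown carbon count for: ", paste(x[is.na(n)], collapse = ", "))
  n * delta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
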