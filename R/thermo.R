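#' Thermodynamic evaluation context
#'
#' Physical constants and conventions for in vivo reaction-energetics:
#' temperature, the gas constant, the CO2 partial pressure of the anaerobic
#' chamber with its Henry's-law constant (aqueous CO2 is never measured
#' directly), a default diphosphate concentration (PPi is not quantified;
#' 100 uM is the conventional intracellular estimate), and the 1 M standard
#' state with unit water activity. The condition metadata (pH 6, ionic
#' strength 0.25 M, pMg 3) are annotation only: the standard transformed
#' energies supplied as priors must already correspond to them.
#'
#' @param temperature_K Temperature (K), default 303.15 (30 C).
#' @param p_co2_atm CO2 partial pressure (atm), default 0.05 (5% chamber).
#' @param henry_kh Henry's-law constant for CO2 (M/atm), default 3.0e-2 at
#'   30 C (implementer-chosen, configurable).
#' @param default_conc Named list of fallback molarities for species absent
#'   from the concentration table; default `list("PPi" = 1e-4)`.
#' @param ph,ionic_strength_M,pmg Condition annotation for the priors.
#' @return A `thermo_context` list; `rt_kj_mol` is precomputed
#'   (`R * T`, with R = 8.314e-3 kJ/mol/K; 2.5204 kJ/mol at 303.15 K).
#' @export
thermo_context <- function(temperature_K = 303.15, p_co2_atm = 0.05,
                           henry_kh = 3.0e-2,
                           default_conc = list("PPi" = 1.0e-4),
                           ph = 6, ionic_strength_M = 0.25, pmg = 3) {
  stopifnot(temperature_K > 0, p_co2_atm >= 0, henry_kh > 0)
  R <- 8.314e-3  # kJ/mol/K
  structure(list(temperature_K = temperature_K, gas_constant = R,
                 rt_kj_mol = R * temperature_K, p_co2_atm = p_co2_atm,
                 henry_kh = henry_kh, default_conc = default_conc,
                 ph = ph, ionic_strength_M = ionic_strength_M, pmg = pmg,
                 standard_state_M = 1),
            class = "thermo_context")
}

#' Aqueous CO2 concentration from Henry's law
#'
#' @param ctx A [thermo_context()].
#' @return `henry_kh * p_co2_atm` (M); 1.5 mM at the defaults.
#' @export
henry_co2 <- function(ctx = thermo_context()) {
  stopifnot(inherits(ctx, "thermo_context"))
  ctx$henry_kh * ctx$p_co2_atm
}

#' Mass-action reaction quotient
#'
#' `Q = prod (c_i / 1 M)^nu_i` over all species of a reaction. Water is
#' excluded (unit activity); species missing from the concentration input
#' fall back to the context defaults (PPi) or Henry's-law CO2. If any
#' species still has no concentration, `Q` is undefined and the missing
#' species are reported.
#'
#' @param rxn One-row slice of a pathway map's `reactions` tibble, or a
#'   reaction id (resolved against `pathway`).
#' @param conc Concentration table (tibble with id + `molarity_M`) or a
#'   named numeric vector of molarities.
#' @param ctx A [thermo_context()].
#' @param pathway Pathway map used when `rxn` is an id.
#' @return List with `q` (NA when undefined) and `missing` (character).
#' @examples
#' reaction_quotient("IspD", zm4_concentrations())
#' @export
reaction_quotient <- function(rxn, conc, ctx = thermo_context(),
                              pathway = mep_pathway()) {
  if (is.character(rxn)) {
    i <- match(rxn, pathway$reactions$id)
    if (is.na(i)) stop("unknown reaction id: ", rxn)
    rxn <- pathway$reactions[i, ]
  }
  st <- rxn$stoichiometry[[1]]
  st <- st[names(st) != "H2O"]
  cv <- if (is.numeric(conc)) conc else concentration_vector(conc)
  defaults <- c(unlist(ctx$default_conc), CO2 = henry_co2(ctx))
  vals <- cv[names(st)]
  names(vals) <- names(st)
  fill <- is.na(vals) & names(st) %in% names(defaults)
  vals[fill] <- defaults[names(st)[fill]]
  missing <- names(st)[is.na(vals)]
  if (length(missing)) {
    return(list(q = NA_real_, missing = missing))
  }
  if (any(vals <= 0)) {
    stop("non-positive concentration for: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  list(q = prod((vals / ctx$standard_state_M)^st), missing = character(0))
}

#' In vivo reaction free energy
#'
#' `deltaG = deltaG0' + RT ln Q`.
#'
#' @param dg0_prime Standard transformed reaction energy (kJ/mol); `NA`
#'   flags the result unavailable.
#' @param q Reaction quotient (> 0).
#' @param ctx A [thermo_context()].
#' @return kJ/mol (NA when `dg0_prime` or `q` is NA).
#' @export
delta_g <- function(dg0_prime, q, ctx = thermo_context()) {
  if (any(!is.na(q) & q <= 0)) stop("reaction quotient must be > 0")
  dg0_prime + ctx$rt_kj_mol * log(q)
}

#' Load standard transformed reaction energies
#'
#' Reads a CSV of `reaction, dg0_prime_kj_mol, se_kj_mol`. The bundled file
#' `dg0_prime_synthetic.csv` contains synthetic stand-in values (plausible
#' magnitudes for pH 6, I = 0.25 M, pMg 3, 30 C, chosen once for testing);
#' for real analyses supply component-contribution estimates computed at the
#' same conditions. IspF and IspG have no entries: the formation energy of
#' MEcDP is too uncertain for the component contribution method.
#'
#' @param path CSV path; default the bundled synthetic file.
#' @return Tibble `reaction`, `dg0_prime_kj_mol`, `se_kj_mol`.
#' @export
load_dg0_priors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dg0_prime_synthetic.csv",
                        package = "mepscope", mustWork = TRUE)
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' In vivo free-energy table for the pathway
#'
#' Evaluates `deltaG = deltaG0' + RT ln Q` for every reaction of the pathway
#' that carries a standard energy prior, using a concentration table plus the
#' context defaults (PPi, CO2). Reactions without a prior (IspF, IspG) or
#' with unmeasured species (IspE: CDP-MEP has no absolute concentration) are
#' flagged, not dropped. The standard-energy standard error is carried
#' through unchanged (concentration uncertainty is not propagated).
#'
#' @param conc Concentration table or named molarity vector.
#' @param ctx A [thermo_context()].
#' @param priors Output of [load_dg0_priors()].
#' @param pathway A `pathway_map`.
#' @return A `dg_table` tibble: `reaction`, `dg0_prime`, `dg0_se`, `q`,
#'   `rt_ln_q`, `dg_in_vivo`, `dg_se`, `flag` (`ok`, `no_dg0_prime`,
#'   `missing_species`), `missing` (list-column).
#' @export
pathway_dg_table <- function(conc, ctx = thermo_context(),
                             priors = load_dg0_priors(),
                             pathway = mep_pathway()) {
  rxns <- pathway$reactions |>
    dplyr::filter(.data$id != "IspS")
  out <- purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    id <- rxns$id[i]
    pi <- match(id, priors$reaction)
    dg0 <- if (is.na(pi)) NA_real_ else priors$dg0_prime_kj_mol[pi]
    se <- if (is.na(pi)) NA_real_ else priors$se_kj_mol[pi]
    qq <- reaction_quotient(rxns[i, ], conc, ctx, pathway)
    rtlnq <- if (is.na(qq$q)) NA_real_ else ctx$rt_kj_mol * log(qq$q)
    flag <- if (is.na(dg0)) "no_dg0_prime"
            else if (length(qq$missing)) "missing_species"
            else "ok"
    tibble::tibble(
      reaction = id, dg0_prime = dg0, dg0_se = se, q = qq$q,
      rt_ln_q = rtlnq,
      dg_in_vivo = if (flag == "ok") dg0 + rtlnq else NA_real_,
      dg_se = se, flag = flag, missing = list(qq$missing)
    )
  })
  new_tbl(out, "dg_table")
}
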