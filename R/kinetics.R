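# Reaction energetics and conventional transition-state-theory kinetics for
# bimolecular H-abstraction: a PES profile (separated reactants -> pre-
# complex -> TS -> post-complex -> products, Gibbs energies on a common
# reference) feeds k = sigma * kappa * (kB T / h) * exp(-dG_act / RT), with
# kappa from the Wigner tunnelling correction when a TS imaginary
# wavenumber is available.

pes_roles <- c(reactant = "reactant", co_reactant = "co_reactant",
               pre_complex = "pre_complex",
               transition_state = "transition_state",
               post_complex = "post_complex", product = "product")

#' Build a potential-energy-surface profile for one reaction
#'
#' Collects the stationary points of one bimolecular reaction (roles
#' `reactant`/`co_reactant`, `pre_complex`, `transition_state`,
#' `post_complex`, `product`) and re-references all Gibbs energies to the
#' pre-reaction complex (RC = 0); absolute values are retained. Separated
#' reactants (and products) are the sums over their constituent species. A
#' transition state below the RC is flagged barrierless rather than
#' rejected.
#'
#' @param species A [species_set()] (or data frame) holding exactly the
#'   species of one reaction, with a `gibbs` column.
#' @param reaction Reaction identifier; default taken from a `reaction`
#'   column or assembled from compound names.
#' @param temperature Temperature in K the energies refer to.
#' @return A `pes_profile` list: `reaction`, `phase`, `temperature`,
#'   `levels` (data frame role/gibbs_abs/gibbs_rel), `barrierless`,
#'   `imag_wavenumber`.
#' @export
build_pes <- function(species, reaction = NULL, temperature = 298.15) {
  df <- as.data.frame(species)
  if (is.null(df$gibbs) || any(is.na(df$gibbs))) {
    stop("build_pes: every species needs a Gibbs energy", call. = FALSE)
  }
  if (length(unique(df$phase)) != 1) {
    stop("build_pes: species span more than one phase", call. = FALSE)
  }
  reaction <- reaction %||% (if (!is.null(df$reaction)) df$reaction[1] else
    paste(df$compound[df$role %in% c("reactant", "co_reactant")],
          collapse = " + "))
  level_of <- function(roles) {
    g <- df$gibbs[df$role %in% roles]
    if (!length(g)) NA_real_ else sum(g)
  }
  levels <- data.frame(
    role = c("reactants", "pre_complex", "transition_state",
             "post_complex", "products"),
    gibbs_abs = c(level_of(c("reactant", "co_reactant")),
                  level_of("pre_complex"),
                  level_of("transition_state"),
                  level_of("post_complex"),
                  level_of("product")),
    stringsAsFactors = FALSE)
  if (is.na(levels$gibbs_abs[levels$role == "pre_complex"])) {
    stop("build_pes: missing pre-reaction complex (RC)", call. = FALSE)
  }
  if (is.na(levels$gibbs_abs[levels$role == "transition_state"])) {
    stop("build_pes: missing transition state", call. = FALSE)
  }
  rc <- levels$gibbs_abs[levels$role == "pre_complex"]
  levels$gibbs_rel <- levels$gibbs_abs - rc
  imag <- df$imag_wavenumber[df$role == "transition_state"]
  imag <- if (length(imag) && !is.na(imag[1])) imag[1] else NA_real_
  out <- list(reaction = reaction, phase = df$phase[1],
              temperature = temperature, levels = levels,
              barrierless = levels$gibbs_rel[
                levels$role == "transition_state"] < 0,
              imag_wavenumber = imag)
  class(out) <- "pes_profile"
  out
}

profile_level <- function(profile, role) {
  profile$levels$gibbs_rel[profile$levels$role == role]
}

#' Activation free energy of a profile
#'
#' G(TS) - G(RC), the barrier relative to the pre-reaction complex (the
#' default energy reference throughout; use
#' `reference_free_energy = "reactants"` conventions explicitly where
#' separated-reactant referencing is wanted, see [reaction_free_energy()]).
#'
#' @param profile A `pes_profile`.
#' @param reference `"pre_complex"` (default) or `"reactants"`.
#' @return Barrier in kcal/mol.
#' @export
activation_free_energy <- function(profile,
                                   reference = c("pre_complex", "reactants")) {
  reference <- match.arg(reference)
  ref <- profile_level(profile, reference)
  if (is.na(ref)) stop("activation_free_energy: reference level '", reference,
                       "' absent from profile", call. = FALSE)
  profile_level(profile, "transition_state") - ref
}

#' Reaction free energy of a profile
#'
#' G(endpoint) - G(RC); the default endpoint is the post-reaction complex
#' (exergonic reactions give negative values), with separated products
#' selectable.
#'
#' @param profile A `pes_profile`.
#' @param endpoint `"post_complex"` (default), `"products"`, or
#'   `"pre_complex"` (trivially 0).
#' @param reference `"pre_complex"` (default) or `"reactants"`.
#' @return Reaction free energy in kcal/mol.
#' @export
reaction_free_energy <- function(profile,
                                 endpoint = c("post_complex", "products",
                                              "pre_complex"),
                                 reference = c("pre_complex", "reactants")) {
  endpoint <- match.arg(endpoint)
  reference <- match.arg(reference)
  e <- profile_level(profile, endpoint)
  r <- profile_level(profile, reference)
  if (is.na(e)) stop("reaction_free_energy: endpoint '", endpoint,
                     "' absent from profile", call. = FALSE)
  if (is.na(r)) stop("reaction_free_energy: reference '", reference,
                     "' absent from profile", call. = FALSE)
  e - r
}

#' Wigner tunnelling correction
#'
#' kappa = 1 + (1/24) * (h c nu / (kB T))^2 for a transition state with
#' imaginary wavenumber nu (cm^-1, magnitude). Always >= 1; tends to 1 as
#' nu -> 0 and grows quadratically in nu.
#'
#' @param imaginary_wavenumber Magnitude of the TS imaginary wavenumber in
#'   cm^-1 (> 0).
#' @param temperature Temperature in K (> 0).
#' @return Dimensionless kappa.
#' @examples
#' wigner_kappa(1500, 298.15)  # about 3.18
#' @export
wigner_kappa <- function(imaginary_wavenumber, temperature = 298.15) {
  if (!is.numeric(imaginary_wavenumber) || any(!is.finite(imaginary_wavenumber)) ||
      any(imaginary_wavenumber <= 0)) {
    stop("wigner_kappa: imaginary wavenumber must be a positive finite number",
         call. = FALSE)
  }
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    stop("wigner_kappa: temperature must be positive", call. = FALSE)
  }
  con <- phys_constants()
  x <- con$planck * con$speed_of_light * imaginary_wavenumber /
    (con$boltzmann * temperature)
  1 + x^2 / 24
}

#' Conventional TST rate constant
#'
#' k = sigma * kappa * (kB T / h) * exp(-dG_act / (R T)). Gibbs activation
#' energies are taken at the 1 M standard state, so the bimolecular rate
#' constant carries units M^-1 s^-1 (numerically identical to the s^-1
#' value the formula yields). Inputs at a 1 atm gas-phase standard state
#' need the opt-in conversion `standard_state_correction`.
#'
#' @param delta_g_activation Activation free energy in kcal/mol.
#' @param temperature Temperature in K (> 0).
#' @param sigma Reaction path degeneracy (positive integer-valued).
#' @param kappa Tunnelling factor (>= 1).
#' @param standard_state_correction If TRUE, adds RT ln(R'T) to convert a
#'   1 atm-referenced barrier to 1 M (R' = 0.082057 L atm mol^-1 K^-1).
#' @return Rate constant (M^-1 s^-1 under the 1 M convention).
#' @examples
#' tst_rate(0)    # the prefactor kB*T/h at 298.15 K, ~6.212e12
#' tst_rate(7.6)  # ~1.67e7
#' @export
tst_rate <- function(delta_g_activation, temperature = 298.15, sigma = 1,
                     kappa = 1, standard_state_correction = FALSE) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    stop("tst_rate: temperature must be positive", call. = FALSE)
  }
  if (!is.numeric(sigma) || any(sigma < 1) ||
      any(abs(sigma - round(sigma)) > 1e-9)) {
    stop("tst_rate: sigma must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(kappa) || any(kappa < 1)) {
    stop("tst_rate: kappa must be >= 1", call. = FALSE)
  }
  con <- phys_constants()
  dg <- delta_g_activation
  if (standard_state_correction) {
    dg <- dg + con$gas_constant_kcal * temperature *
      log(0.0820573660809596 * temperature)
  }
  sigma * kappa * (con$boltzmann * temperature / con$planck) *
    exp(-dg / (con$gas_constant_kcal * temperature))
}

#' Rate table over a set of PES profiles
#'
#' One rate result per reaction — activation and reaction free energies,
#' sigma, kappa (Wigner from the TS imaginary wavenumber when present,
#' otherwise the supplied default), temperature and TST rate constant —
#' ranked by rate constant descending. The fastest reaction and the
#' lowest-barrier reaction are flagged; with consistent profiles these
#' coincide.
#'
#' @param profiles List of `pes_profile` objects.
#' @param sigma Single degeneracy or named vector per reaction id.
#' @param kappa Default tunnelling factor for profiles without an imaginary
#'   wavenumber.
#' @param endpoint Endpoint for the reaction free energy (see
#'   [reaction_free_energy()]).
#' @return Data frame (class `rate_table`) ranked by `rate_constant`
#'   descending, with logical flags `fastest` and `min_barrier`.
#' @export
rate_table <- function(profiles, sigma = 1, kappa = 1,
                       endpoint = "post_complex") {
  if (inherits(profiles, "pes_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    sg <- if (length(sigma) > 1 || !is.null(names(sigma))) {
      s <- sigma[p$reaction]
      if (is.na(s)) 1 else unname(s)
    } else sigma
    kp <- if (!is.na(p$imag_wavenumber)) {
      wigner_kappa(p$imag_wavenumber, p$temperature)
    } else kappa
    dga <- activation_free_energy(p)
    data.frame(reaction = p$reaction,
               delta_g_activation = dga,
               delta_g_reaction = reaction_free_energy(p, endpoint),
               sigma = sg, kappa = kp, temperature = p$temperature,
               rate_constant = tst_rate(dga, p$temperature, sg, kp),
               barrierless = p$barrierless,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rate_constant, out$reaction), , drop = FALSE]
  out$fastest <- seq_len(nrow(out)) == 1L
  out$min_barrier <- out$delta_g_activation == min(out$delta_g_activation)
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Bundled kinetics reference table for Pt-3-O-glc + ·OH
#'
#' Gas-phase 298.15 K activation free energies, reaction free energies
#' (both relative to the pre-reaction complex) and published reference rate
#' constants for hydroxyl-radical H-abstraction at the 3'-OH, 4'-OH, 5-OH
#' and 7-OH sites of Pt-3-O-glc. The `k_ref` column is carried as published
#' for ranking comparisons only: the sigma/kappa/reference-state settings
#' behind those absolute values are not recoverable from the printed data,
#' so this package never presents a recomputed k as a reproduction of them.
#'
#' @return Data frame `reaction`, `site`, `phase`, `temperature`,
#'   `delta_g_reaction`, `delta_g_activation`, `k_ref`.
#' @export
table2_kinetics <- function() {
  df <- read_delim_auto(
    system.file("extdata", "table2_kinetics.csv", package = "radscav",
                mustWork = TRUE))
  df$site <- normalize_site(df$site)
  df
}

#' PES profiles reconstructed from the bundled kinetics table
#'
#' Builds one `pes_profile` per reaction of [table2_kinetics()] via the
#' synthetic generator, placing the TS at the published barrier and the
#' post-complex at the published reaction free energy (both relative to
#' RC = 0).
#'
#' @param complexation RC and PC complexation depths in kcal/mol used for
#'   the separated-species levels (presentation only; barriers and reaction
#'   energies are RC-referenced and unaffected).
#' @return List of `pes_profile` objects.
#' @export
table2_profiles <- function(complexation = 2) {
  table2_profiles_from(table2_kinetics(), complexation)
}
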