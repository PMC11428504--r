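# Synthetic thermochemistry: the inverse of the descriptor equations.
# Given target descriptor values, construct a species set whose enthalpies
# reproduce them exactly; given target barriers and reaction energies,
# construct a stationary-point list whose PES profile reproduces them.
# These generators stand in for quantum-chemistry runs, so every pipeline
# stage is testable offline, with optional seeded Gaussian noise as the
# simplest model of method error.

#' Generate a species set from target descriptor values
#'
#' For each target row (compound, site, phase, any subset of bde/ip/pde/
#' pa/ete in kcal/mol) the generator inverts the descriptor equations:
#' parent at the base enthalpy, radical at base + BDE - H(H·), radical
#' cation at base + IP - H(e-), anion at base + PA - H(H+); targets given
#' only as two-step pairs are mapped through the Hess identities (e.g. BDE
#' = IP + PDE - C). All routes implied by the supplied targets must agree:
#' any implied-value conflict above `tol` (for instance IP + PDE != PA +
#' ETE, or an IP that varies across sites of one compound-phase) rejects
#' the row by name. Recomputing descriptors on the noiseless output
#' recovers every target to machine precision; `tol` can be relaxed (e.g.
#' to 0.3 kcal/mol) to regenerate rounded printed tables.
#'
#' @param targets Data frame with columns `compound`, `site`, `phase` and
#'   any of `bde`, `ip`, `pde`, `pa`, `ete`.
#' @param refs `reference_enthalpies` covering the target phases.
#' @param base_enthalpy Parent enthalpy in kcal/mol (arbitrary; descriptors
#'   are invariant under a uniform shift).
#' @param noise_sd Standard deviation (kcal/mol) of independent Gaussian
#'   noise added to every enthalpy; 0 (default) for exact construction.
#' @param seed Integer seed for the noise (R's Mersenne-Twister); required
#'   when `noise_sd > 0` for reproducibility.
#' @param tol Internal-consistency tolerance in kcal/mol.
#' @return A validated [species_set()].
#' @export
make_species_set <- function(targets, refs = default_reference_enthalpies(),
                             base_enthalpy = -1000, noise_sd = 0,
                             seed = NULL, tol = 1e-9) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  need <- c("compound", "site", "phase")
  miss <- setdiff(need, names(targets))
  if (length(miss)) {
    stop("make_species_set: targets missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (d in descriptor_names()) {
    if (is.null(targets[[d]])) targets[[d]] <- NA_real_
  }
  targets$site <- normalize_site(targets$site)
  if (noise_sd < 0) stop("make_species_set: noise_sd must be >= 0", call. = FALSE)

  rows <- list()
  add <- function(compound, role, site, phase, enthalpy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      compound = compound, role = role, site = site, phase = phase,
      enthalpy = enthalpy, stringsAsFactors = FALSE)
  }
  for (cp in unique(targets$compound)) {
    for (ph in unique(targets$phase[targets$compound == cp])) {
      sub <- targets[targets$compound == cp & targets$phase == ph, , drop = FALSE]
      rr <- ref_row(refs, ph)
      C <- rr$h_proton + rr$h_electron - rr$h_hydrogen_atom
      add(cp, "parent", NA_character_, ph, base_enthalpy)
      cation_vals <- numeric(0)
      for (i in seq_len(nrow(sub))) {
        t <- sub[i, ]
        rowname <- paste0(cp, " ", t$site, " [", ph, "]")
        # implied BDE by each available route
        impl <- c(direct = t$bde,
                  setpt = if (!is.na(t$ip) && !is.na(t$pde)) t$ip + t$pde - C else NA,
                  splet = if (!is.na(t$pa) && !is.na(t$ete)) t$pa + t$ete - C else NA)
        impl <- impl[!is.na(impl)]
        if (length(impl) > 1 && diff(range(impl)) > tol) {
          stop("make_species_set: inconsistent targets for ", rowname,
               " (implied BDE spread ",
               format(diff(range(impl)), digits = 3),
               " kcal/mol exceeds tol)", call. = FALSE)
        }
        bde_val <- if (length(impl)) impl[[1]] else NA_real_
        if (!is.na(bde_val)) {
          add(cp, "radical", t$site, ph,
              base_enthalpy + bde_val - rr$h_hydrogen_atom)
        }
        # anion from PA directly, else from ETE via the radical
        pa_val <- if (!is.na(t$pa)) t$pa else
          if (!is.na(t$ete) && !is.na(bde_val)) bde_val + C - t$ete else NA_real_
        if (!is.na(pa_val)) {
          add(cp, "anion", t$site, ph, base_enthalpy + pa_val - rr$h_proton)
        }
        # cation from IP directly, else from PDE via the radical
        ip_val <- if (!is.na(t$ip)) t$ip else
          if (!is.na(t$pde) && !is.na(bde_val)) bde_val + C - t$pde else NA_real_
        if (!is.na(ip_val)) cation_vals <- c(cation_vals, ip_val)
      }
      if (length(cation_vals)) {
        if (diff(range(cation_vals)) > tol) {
          stop("make_species_set: IP targets vary across sites of ", cp,
               " [", ph, "] by ",
               format(diff(range(cation_vals)), digits = 3),
               " kcal/mol (IP involves no site)", call. = FALSE)
        }
        add(cp, "radical_cation", NA_character_, ph,
            base_enthalpy + cation_vals[1] - rr$h_electron)
      }
    }
  }
  set <- species_set(do.call(rbind, rows),
                     metadata = list(generator = "make_species_set",
                                     base_enthalpy = base_enthalpy,
                                     noise_sd = noise_sd, seed = seed))
  if (noise_sd > 0) set <- perturb(set, noise_sd, seed)
  set
}

#' Generate stationary-point lists from target PES quantities
#'
#' One reaction per target row: separated reactants at the base Gibbs
#' energy, the pre-reaction complex (RC) `rc_complexation` below them, the
#' TS at RC + `barrier`, the post-complex (PC) at RC + `reaction_energy`,
#' and separated products `pc_complexation` above the PC. Feeding the
#' output to [build_pes()] and [activation_free_energy()] returns the
#' target barrier exactly. A zero or negative barrier is allowed and
#' surfaces as the profile's `barrierless` flag.
#'
#' @param targets Data frame with columns `reaction`, `barrier`,
#'   `reaction_energy` and optionally `rc_complexation`, `pc_complexation`
#'   (default 2 kcal/mol each), `imag_wavenumber`, `temperature` (default
#'   298.15 K), `phase` (default "gas").
#' @param base_gibbs Gibbs energy of the separated reactants (arbitrary
#'   common reference).
#' @param noise_sd,seed Optional seeded Gaussian perturbation of all Gibbs
#'   energies (kcal/mol).
#' @return Data frame of stationary points (`reaction`, `compound`, `role`,
#'   `phase`, `enthalpy`, `gibbs`, `imag_wavenumber`, `temperature`), ready
#'   for [build_pes()] after splitting by reaction.
#' @export
make_pes <- function(targets, base_gibbs = -1000, noise_sd = 0, seed = NULL) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  need <- c("reaction", "barrier", "reaction_energy")
  miss <- setdiff(need, names(targets))
  if (length(miss)) {
    stop("make_pes: targets missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(targets$rc_complexation)) targets$rc_complexation <- 2
  if (is.null(targets$pc_complexation)) targets$pc_complexation <- 2
  if (is.null(targets$temperature)) targets$temperature <- 298.15
  if (is.null(targets$phase)) targets$phase <- "gas"
  if (is.null(targets$imag_wavenumber)) targets$imag_wavenumber <- NA_real_
  if (noise_sd < 0) stop("make_pes: noise_sd must be >= 0", call. = FALSE)

  out <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    rc <- base_gibbs - t$rc_complexation
    g <- c(reactant = base_gibbs, pre_complex = rc,
           transition_state = rc + t$barrier,
           post_complex = rc + t$reaction_energy,
           product = rc + t$reaction_energy + t$pc_complexation)
    data.frame(reaction = t$reaction,
               compound = paste0(t$reaction, ":", names(g)),
               role = names(g), site = NA_character_, phase = t$phase,
               enthalpy = unname(g), gibbs = unname(g),
               imag_wavenumber = ifelse(names(g) == "transition_state",
                                        t$imag_wavenumber, NA_real_),
               temperature = t$temperature,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (noise_sd > 0) {
    if (is.null(seed)) stop("make_pes: seed required when noise_sd > 0",
                            call. = FALSE)
    out$gibbs <- out$gibbs + local_rnorm(nrow(out), noise_sd, seed)
    out$enthalpy <- out$gibbs
  }
  out
}

# seeded draws that do not disturb the caller's RNG state
local_rnorm <- function(n, sd, seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  stats::rnorm(n, mean = 0, sd = sd)
}

#' Perturb a species set with seeded Gaussian noise
#'
#' Adds independent N(0, noise_sd^2) noise to every enthalpy (and Gibbs
#' energy where present). `noise_sd = 0` is the identity; the same seed
#' always reproduces the same output (Mersenne-Twister, inversion normals —
#' fixed so seeds are portable across platforms).
#'
#' @param set A [species_set()].
#' @param noise_sd Noise standard deviation in kcal/mol (>= 0).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return The perturbed, re-validated [species_set()].
#' @export
perturb <- function(set, noise_sd, seed = NULL) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || is.na(noise_sd) ||
      noise_sd < 0) {
    stop("perturb: noise_sd must be a single non-negative number",
         call. = FALSE)
  }
  if (noise_sd == 0) return(set)
  if (is.null(seed)) stop("perturb: seed required when noise_sd > 0",
                          call. = FALSE)
  df <- as.data.frame(set)
  eps <- local_rnorm(nrow(df), noise_sd, seed)
  df$enthalpy <- df$enthalpy + eps
  if (!is.null(df$gibbs)) df$gibbs <- ifelse(is.na(df$gibbs), NA_real_,
                                             df$gibbs + eps)
  md <- attr(set, "metadata") %||% list()
  md$perturbed <- list(noise_sd = noise_sd, seed = seed)
  species_set(df, metadata = md)
}

#' Random consistent descriptor targets
#'
#' Draws target rows in physically plausible ranges (BDE 70-110, IP 120-260,
#' PA 20-280 kcal/mol) and completes PDE and ETE through the Hess identities
#' so every row is exactly constructible; used for round-trip validation of
#' the generator at scale.
#'
#' @param n Number of target rows.
#' @param seed Integer seed.
#' @param phase Phase label (must exist in `refs`).
#' @param refs `reference_enthalpies`.
#' @return Targets data frame acceptable to [make_species_set()].
#' @export
random_descriptor_targets <- function(n, seed, phase = "gas",
                                      refs = default_reference_enthalpies()) {
  C <- unname(reference_constant(refs, phase))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  sites <- canonical_sites()
  data.frame(
    compound = paste0("syn", seq_len(n)),
    site = sample(sites, n, replace = TRUE),
    phase = phase,
    bde = stats::runif(n, 70, 110),
    ip = stats::runif(n, 120, 260),
    pa = stats::runif(n, 20, 280),
    stringsAsFactors = FALSE) -> t
  t$pde <- t$bde + C - t$ip
  t$ete <- t$bde + C - t$pa
  t
}
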