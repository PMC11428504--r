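#' @importFrom stats setNames
NULL

# Canonical phenolic sites of the anthocyanin benzopyrylium skeleton, in the
# fixed comparison order used for tie-breaking (B-ring primed positions
# before A-ring positions).
canonical_sites <- function() {
  c("3\u2032-OH", "4\u2032-OH", "5\u2032-OH", "5-OH", "7-OH")
}

species_roles <- c("parent", "radical", "anion", "radical_cation",
                   "transition_state", "pre_complex", "post_complex",
                   "product", "co_reactant", "reactant")

spin_states <- c("singlet", "doublet", "triplet")

#' Normalise phenolic site labels
#'
#' Primed positions may be written with an ASCII apostrophe (`4'-OH`) or the
#' Unicode prime (`4′-OH`); both map to the same canonical label so that
#' user tables, bundled fixtures and code agree. Whitespace is trimmed;
#' unknown labels pass through unchanged (free-text extension sites are
#' allowed).
#'
#' @param x Character vector of site labels (NA allowed).
#' @return Canonicalised character vector.
#' @examples
#' normalize_site(c("4'-OH", "5-OH"))
#' @export
normalize_site <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("['\u02b9\u2019\u00b4]", "\u2032", x)
  x[!nzchar(x)] <- NA_character_
  x
}

# order key: canonical sites first in fixed order, then others alphabetically
site_order_key <- function(sites) {
  i <- match(sites, canonical_sites())
  extra <- sort(unique(sites[is.na(i) & !is.na(sites)]))
  i[is.na(i)] <- length(canonical_sites()) +
    match(sites[is.na(i)], extra)
  i
}

#' Construct and validate a species set
#'
#' A species set is the unit record of the pipeline: one row per chemical
#' entity (a parent phenol, its phenoxyl radical, phenolate anion, radical
#' cation, or a stationary point of a reaction path) in one phase, with its
#' enthalpy and optionally Gibbs energy in kcal/mol. Validation enforces the
#' structural invariants every downstream stage assumes: finite enthalpies,
#' known roles, unique (compound, role, site, phase, spin) keys, transition
#' states carrying Gibbs energies and positive imaginary wavenumbers, and no
#' orphan derived species (each radical/anion/radical cation needs its parent
#' in the same compound and phase).
#'
#' @param df Data frame with columns `compound`, `role`, `phase`, `enthalpy`
#'   and optionally `site`, `gibbs`, `imag_wavenumber`, `spin`, `reaction`.
#' @param metadata Free-form provenance list stored as an attribute.
#' @return The validated data frame with class `species_set`.
#' @export
species_set <- function(df, metadata = list()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("compound", "role", "phase", "enthalpy")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("species table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("site", "spin")) if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  for (opt in c("gibbs", "imag_wavenumber")) if (is.null(df[[opt]])) df[[opt]] <- NA_real_
  df$site <- normalize_site(df$site)
  df$spin[!is.na(df$spin) & !nzchar(trimws(df$spin))] <- NA_character_

  bad_role <- !df$role %in% species_roles
  if (any(bad_role)) {
    stop("species table: unknown role(s) in row(s) ",
         paste(which(bad_role), collapse = ", "), ": ",
         paste(unique(df$role[bad_role]), collapse = ", "), call. = FALSE)
  }
  bad_spin <- !is.na(df$spin) & !df$spin %in% spin_states
  if (any(bad_spin)) {
    stop("species table: unknown spin state in row(s) ",
         paste(which(bad_spin), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$enthalpy) || any(!is.finite(df$enthalpy))) {
    stop("species table: non-finite enthalpy in row(s) ",
         paste(which(!is.finite(suppressWarnings(as.numeric(df$enthalpy)))),
               collapse = ", "), call. = FALSE)
  }
  ts <- df$role == "transition_state"
  if (any(ts & is.na(df$gibbs))) {
    stop("species table: transition state without Gibbs energy in row(s) ",
         paste(which(ts & is.na(df$gibbs)), collapse = ", "), call. = FALSE)
  }
  bad_imag <- !is.na(df$imag_wavenumber) & ts & df$imag_wavenumber <= 0
  if (any(bad_imag)) {
    stop("species table: non-positive imaginary wavenumber in row(s) ",
         paste(which(bad_imag), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$compound, df$role, df$site, df$phase, df$spin, sep = "\r")
  if (anyDuplicated(key)) {
    stop("species table: duplicate (compound, role, site, phase, spin) key ",
         "in row(s) ", paste(which(duplicated(key)), collapse = ", "),
         call. = FALSE)
  }
  derived <- df$role %in% c("radical", "anion", "radical_cation")
  if (any(derived)) {
    parent_key <- paste(df$compound, df$phase, sep = "\r")[df$role == "parent"]
    orphan <- derived & !(paste(df$compound, df$phase, sep = "\r") %in% parent_key)
    if (any(orphan)) {
      stop("species table: derived species without a parent record in the ",
           "same compound and phase, row(s) ",
           paste(which(orphan), collapse = ", "), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  attr(df, "metadata") <- metadata
  class(df) <- c("species_set", "data.frame")
  df
}

#' Read a species thermochemistry table
#'
#' Reads the delimited text dialect documented in the package: UTF-8, comma
#' or tab separated (auto-detected), one row per species, columns
#' `compound | role | site | phase | enthalpy | gibbs | imag_wavenumber | spin`.
#' A leading comment line `# units: hartree` declares hartree energies, which
#' are converted to kcal/mol on ingest (default `# units: kcal/mol`).
#'
#' @param path Path to the table.
#' @return A validated [species_set()].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("# units: kcal/mol",
#'   "compound,role,site,phase,enthalpy",
#'   "X,parent,,gas,-1000",
#'   "X,radical,4'-OH,gas,-913.8"), tf)
#' read_species_table(tf)
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path, call. = FALSE)
  df <- read_delim_auto(path, comment_keys = TRUE)
  keys <- attr(df, "header_keys") %||% list()
  unit <- tolower(keys$units %||% "kcal/mol")
  if (!unit %in% c("kcal/mol", "kcalmol", "kcal", "hartree")) {
    stop("species table: unknown unit declaration '", unit, "'", call. = FALSE)
  }
  if (unit == "hartree") {
    fac <- phys_constants()$hartree_kcalmol
    for (col in intersect(c("enthalpy", "gibbs"), names(df))) {
      df[[col]] <- df[[col]] * fac  # NA-safe; one conversion at the boundary
    }
  }
  species_set(df, metadata = list(source = path, units_in = unit))
}

#' Write a species set back to delimited text
#'
#' Writes the same dialect [read_species_table()] reads (tab-separated,
#' kcal/mol), so that a load/write/load cycle is the identity on all fields.
#'
#' @param set A [species_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(set, path) {
  set <- species_set(as.data.frame(set), attr(set, "metadata") %||% list())
  cols <- intersect(c("reaction", "compound", "role", "site", "phase",
                      "enthalpy", "gibbs", "imag_wavenumber", "spin"),
                    names(set))
  write_delim_utf8(as.data.frame(set)[, cols],
                   path, header_lines = "units: kcal/mol")
}

#' Look up one species record
#'
#' Keyed retrieval with explicit failure: a missing record is an error, and
#' when several spin states of the same species exist the caller must either
#' request one (`spin = "singlet"`) or opt into the lowest-enthalpy default
#' (`spin = "lowest"`); an unqualified lookup never silently returns an
#' arbitrary spin state.
#'
#' @param set A [species_set()].
#' @param compound,role,phase Key fields.
#' @param site Site label or NA for site-free species (parents, cations).
#' @param spin NULL (error if ambiguous), a spin state, or `"lowest"`.
#' @return One-row `species_set`.
#' @export
species_lookup <- function(set, compound, role, site = NA, phase,
                           spin = NULL) {
  df <- as.data.frame(set)
  site <- normalize_site(site)
  hit <- df$compound == compound & df$role == role & df$phase == phase &
    (is.na(site) & is.na(df$site) | !is.na(site) & !is.na(df$site) & df$site == site)
  sub <- df[hit, , drop = FALSE]
  key <- paste0(compound, " / ", role, " / ", if (is.na(site)) "-" else site,
                " / ", phase)
  if (!nrow(sub)) stop("species not found: ", key, call. = FALSE)
  if (nrow(sub) > 1) {
    if (is.null(spin)) {
      stop("ambiguous species (multiple spin states: ",
           paste(sub$spin, collapse = ", "), ") for ", key,
           "; request a spin state explicitly", call. = FALSE)
    }
    sub <- if (identical(spin, "lowest")) {
      sub[which.min(sub$enthalpy), , drop = FALSE]
    } else {
      sub[!is.na(sub$spin) & sub$spin == spin, , drop = FALSE]
    }
    if (!nrow(sub)) stop("species not found for spin '", spin, "': ", key,
                         call. = FALSE)
  }
  rownames(sub) <- NULL
  class(sub) <- c("species_set", "data.frame")
  sub
}
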