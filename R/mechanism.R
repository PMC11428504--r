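# Decision layer: which radical-scavenging route is thermodynamically
# preferred, per compound and phase. The route whose first/committing step
# is cheapest wins: min-site BDE (HAT) vs IP (SET-PT) vs min-site PA (SPLET).

#' Most active site for a descriptor
#'
#' Site with the minimal descriptor value for one compound and phase. Ties
#' break deterministically by the canonical site order 3' < 4' < 5' < 5 < 7
#' (non-canonical free-text sites sort after, alphabetically).
#'
#' @param table A [descriptor_table()].
#' @param compound,phase Selection.
#' @param descriptor One of `"bde"`, `"pde"`, `"pa"`, `"ete"` (or `"ip"`,
#'   which is site-free and returns the first site row carrying it).
#' @return List with `site` and `value`.
#' @export
min_site <- function(table, compound, phase, descriptor) {
  table <- descriptor_table(table)
  descriptor <- match.arg(descriptor, descriptor_names())
  df <- as.data.frame(table)
  df <- df[df$compound == compound & df$phase == phase &
             !is.na(df[[descriptor]]), , drop = FALSE]
  if (!nrow(df)) {
    stop("min_site: descriptor '", descriptor, "' not computable for ",
         compound, " in ", phase, " (absent everywhere)", call. = FALSE)
  }
  df <- df[order(df[[descriptor]], site_order_key(df$site)), , drop = FALSE]
  list(site = df$site[1], value = df[[descriptor]][1])
}

#' Rank compounds by a descriptor at one site and phase
#'
#' Ascending order (most active first for cost-type descriptors); ties break
#' alphabetically by compound. Compounds lacking the row are dropped with a
#' warning and listed in the `unranked` attribute.
#'
#' @inheritParams min_site
#' @param site Site label.
#' @param compounds Optional compound subset; default all in the table.
#' @return Data frame `compound`, `value`, ascending; attribute `unranked`.
#' @export
rank_compounds <- function(table, descriptor, site, phase, compounds = NULL) {
  table <- descriptor_table(table)
  descriptor <- match.arg(descriptor, descriptor_names())
  site <- normalize_site(site)
  df <- as.data.frame(table)
  compounds <- compounds %||% unique(df$compound)
  df <- df[df$compound %in% compounds & df$phase == phase &
             !is.na(df$site) & df$site == site &
             !is.na(df[[descriptor]]), , drop = FALSE]
  unranked <- setdiff(compounds, df$compound)
  if (length(unranked)) {
    warning("rank_compounds: no ", descriptor, " row at ", site, " (", phase,
            ") for: ", paste(unranked, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df[[descriptor]], df$compound), , drop = FALSE]
  out <- data.frame(compound = df$compound, value = df[[descriptor]],
                    stringsAsFactors = FALSE)
  attr(out, "unranked") <- unranked
  out
}

#' Classify the preferred radical-scavenging mechanism
#'
#' Compares the committing-step costs of the three routes — the minimal-site
#' BDE (HAT), the IP (SET-PT first step) and the minimal-site PA (SPLET
#' first step) — and returns the route with the smallest cost. Exact ties
#' resolve in the fixed priority HAT > SET-PT > SPLET and are flagged.
#'
#' @inheritParams min_site
#' @return A `mechanism_verdict` list: `compound`, `phase`, `mechanism`, the
#'   `evidence` triple with winning sites, and `tie`.
#' @export
classify_mechanism <- function(table, compound, phase) {
  table <- descriptor_table(table)
  df <- as.data.frame(table)
  sub <- df[df$compound == compound & df$phase == phase, , drop = FALSE]
  if (!nrow(sub)) {
    stop("classify_mechanism: no rows for ", compound, " in ", phase,
         call. = FALSE)
  }
  missing_leg <- c(bde = all(is.na(sub$bde)), ip = all(is.na(sub$ip)),
                   pa = all(is.na(sub$pa)))
  if (any(missing_leg)) {
    stop("classify_mechanism: not computable for ", compound, " in ", phase,
         ": descriptor(s) absent: ",
         paste(names(missing_leg)[missing_leg], collapse = ", "),
         call. = FALSE)
  }
  b <- min_site(table, compound, phase, "bde")
  p <- min_site(table, compound, phase, "pa")
  ipv <- sub$ip[!is.na(sub$ip)][1]
  costs <- c(HAT = b$value, `SET-PT` = ipv, SPLET = p$value)
  win <- names(costs)[which.min(costs)]  # which.min: first of tied minima,
  # and the vector is ordered HAT, SET-PT, SPLET — the documented priority
  verdict <- list(
    compound = compound, phase = phase, mechanism = win,
    evidence = list(min_bde = b, ip = ipv, min_pa = p),
    tie = sum(costs == min(costs)) > 1L)
  class(verdict) <- "mechanism_verdict"
  verdict
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat(sprintf("%s [%s]: %s  (min BDE %s @ %s | IP %s | min PA %s @ %s)%s\n",
              x$compound, x$phase, x$mechanism,
              format_energy(x$evidence$min_bde$value), x$evidence$min_bde$site,
              format_energy(x$evidence$ip),
              format_energy(x$evidence$min_pa$value), x$evidence$min_pa$site,
              if (x$tie) "  [tie]" else ""))
  invisible(x)
}

#' Mechanism verdicts for every compound-phase in a table
#'
#' @param table A [descriptor_table()].
#' @return Data frame with one row per (compound, phase): `mechanism`,
#'   `min_bde`, `min_bde_site`, `ip`, `min_pa`, `min_pa_site`, `tie`.
#' @export
classify_all <- function(table) {
  table <- descriptor_table(table)
  df <- as.data.frame(table)
  combos <- unique(df[, c("compound", "phase")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    v <- classify_mechanism(table, combos$compound[i], combos$phase[i])
    data.frame(compound = v$compound, phase = v$phase, mechanism = v$mechanism,
               min_bde = v$evidence$min_bde$value,
               min_bde_site = v$evidence$min_bde$site,
               ip = v$evidence$ip,
               min_pa = v$evidence$min_pa$value,
               min_pa_site = v$evidence$min_pa$site,
               tie = v$tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Solvent shift of a descriptor between two phases
#'
#' Per-compound shift value(phase_a) - value(phase_b) and its unweighted mean
#' over compounds. IP is a single value per compound-phase; site-dependent
#' descriptors are first averaged over the sites present in both phases for
#' that compound (documented convention).
#'
#' @inheritParams min_site
#' @param phase_a,phase_b Phase labels (shift is a minus b, so gas vs water
#'   gives the decrease on solvation as a positive number when a > b).
#' @return List with `per_compound` (data frame) and `mean`.
#' @export
solvent_shift_summary <- function(table, descriptor, phase_a, phase_b) {
  table <- descriptor_table(table)
  descriptor <- match.arg(descriptor, descriptor_names())
  df <- as.data.frame(table)
  value_of <- function(cp, ph) {
    if (descriptor == "ip") {
      x <- df$ip[df$compound == cp & df$phase == ph]
      x <- x[!is.na(x)]
      if (length(x)) x[1] else NA_real_
    } else {
      a <- df[df$compound == cp & df$phase == phase_a, c("site", descriptor)]
      b <- df[df$compound == cp & df$phase == phase_b, c("site", descriptor)]
      shared <- intersect(a$site[!is.na(a[[descriptor]])],
                          b$site[!is.na(b[[descriptor]])])
      if (!length(shared)) return(NA_real_)
      src <- if (ph == phase_a) a else b
      mean(src[[descriptor]][match(shared, src$site)])
    }
  }
  comps <- sort(unique(df$compound))
  per <- data.frame(
    compound = comps,
    shift = vapply(comps, function(cp) {
      va <- value_of(cp, phase_a)
      vb <- value_of(cp, phase_b)
      va - vb
    }, numeric(1)),
    stringsAsFactors = FALSE)
  per <- per[!is.na(per$shift), , drop = FALSE]
  if (!nrow(per)) {
    stop("solvent_shift_summary: no compound has '", descriptor,
         "' in both phases", call. = FALSE)
  }
  rownames(per) <- NULL
  list(per_compound = per, mean = mean(per$shift))
}

#' Substituent contrast for a descriptor
#'
#' Mean difference between a reference compound and one or more contrast
#' compounds at a fixed site and phase: mean over contrasts of
#' (reference value - contrast value). Quantifies, e.g., how much a B-ring
#' hydroxy/methoxy substitution lowers the 4'-OH BDE relative to the
#' mono-substituted compound.
#'
#' @inheritParams rank_compounds
#' @param reference_compound Reference compound label.
#' @param contrast_compounds Character vector of contrast compounds.
#' @return Mean difference in kcal/mol.
#' @export
substituent_contrast <- function(table, descriptor, site, phase,
                                 reference_compound, contrast_compounds) {
  table <- descriptor_table(table)
  descriptor <- match.arg(descriptor, descriptor_names())
  site <- normalize_site(site)
  df <- as.data.frame(table)
  grab <- function(cp) {
    x <- df[df$compound == cp & df$phase == phase &
              !is.na(df$site) & df$site == site, descriptor]
    x <- x[!is.na(x)]
    if (!length(x)) {
      stop("substituent_contrast: no ", descriptor, " row for ", cp, " at ",
           site, " (", phase, ")", call. = FALSE)
    }
    x[1]
  }
  ref_val <- grab(reference_compound)
  mean(vapply(contrast_compounds, function(cp) ref_val - grab(cp), numeric(1)))
}

#' Second hydrogen-atom-transfer (double HAT) channel analysis
#'
#' After the first HAT at the most active site, the phenoxyl radical of a
#' catechol/guaiacyl-bearing compound can lose a second H·, closing to a
#' benzodioxole (via an ortho-methoxy CH) or an o-quinone (via the ortho
#' hydroxyl). Each channel's second-step cost is evaluated in the same form
#' as the first step, H(product) + H(H·) - H(first radical); the favoured
#' channel is the cheapest. When a product exists in several spin states the
#' lowest-enthalpy state is used (overridable via the species records passed
#' in), and the chosen state is recorded.
#'
#' @param parent One-row parent species (same compound/phase, used for
#'   validation and labelling).
#' @param first_radical One-row `radical` species, the first-HAT product.
#' @param channel_products A [species_set()] (or data frame) of `product`
#'   role records, one or more spin states per product name (`compound`
#'   column carries the product name).
#' @param refs `reference_enthalpies` covering the phase.
#' @return A `second_hat_result` list: `compound`, `phase`, `first_site`,
#'   `channels` (data frame product/spin/cost, ascending cost) and `favored`.
#' @export
second_hat_analysis <- function(parent, first_radical, channel_products,
                                refs) {
  parent <- one_species(parent, "parent", "second_hat_analysis")
  first_radical <- one_species(first_radical, "radical", "second_hat_analysis")
  check_same(parent, first_radical, "second_hat_analysis")
  prods <- as.data.frame(channel_products)
  if (!nrow(prods)) {
    stop("second_hat_analysis: no channel products supplied", call. = FALSE)
  }
  if (!all(prods$role == "product")) {
    stop("second_hat_analysis: channel species must have role 'product'",
         call. = FALSE)
  }
  if (!all(prods$phase == parent$phase)) {
    stop("second_hat_analysis: channel product phase mismatch", call. = FALSE)
  }
  h_h <- ref_row(refs, parent$phase)$h_hydrogen_atom
  # lowest-enthalpy spin state per product name
  pick <- do.call(rbind, lapply(split(prods, prods$compound), function(g) {
    g[which.min(g$enthalpy), , drop = FALSE]
  }))
  channels <- data.frame(
    product = pick$compound,
    spin = if (is.null(pick$spin)) NA_character_ else pick$spin,
    cost = pick$enthalpy + h_h - first_radical$enthalpy,
    stringsAsFactors = FALSE)
  channels <- channels[order(channels$cost, channels$product), , drop = FALSE]
  rownames(channels) <- NULL
  out <- list(compound = parent$compound, phase = parent$phase,
              first_site = first_radical$site, channels = channels,
              favored = channels$product[1])
  class(out) <- "second_hat_result"
  out
}

#' Bundled double-HAT channel costs for Pt-3-O-glc
#'
#' Second-step energy costs (kcal/mol) of the two closure channels of the
#' Pt-3-O-glc 4'-O phenoxyl radical — benzodioxole formation via the
#' C5'-OCH3 group and (singlet) o-quinone formation via the C3'-OH group —
#' in gas, water and ethanol, transcribed from the published double-HAT
#' scheme.
#'
#' @return Data frame `compound`, `first_site`, `product`, `spin`, `phase`,
#'   `second_step_cost`.
#' @export
fig2_double_hat <- function() {
  df <- read_delim_auto(
    system.file("extdata", "fig2_double_hat.csv", package = "radscav",
                mustWork = TRUE))
  df$site <- NULL
  df$first_site <- normalize_site(df$first_site)
  df
}

#' Favoured double-HAT channel per phase from a cost table
#'
#' @param costs Data frame as returned by [fig2_double_hat()].
#' @return Data frame per phase: `favored`, `cost`, `margin` (runner-up cost
#'   minus winner cost).
#' @export
second_hat_from_costs <- function(costs) {
  do.call(rbind, lapply(split(costs, costs$phase), function(g) {
    g <- g[order(g$second_step_cost, g$product), , drop = FALSE]
    data.frame(compound = g$compound[1], phase = g$phase[1],
               favored = g$product[1], cost = g$second_step_cost[1],
               margin = if (nrow(g) > 1) g$second_step_cost[2] - g$second_step_cost[1] else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
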