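#' Per-OTU prevalence within one site and condition
#'
#' Fraction of the group's samples in which the OTU is detected (count > 0).
#'
#' @param table an [otu_table()].
#' @param meta a [sample_metadata()].
#' @param site `"tongue"` or `"saliva"`.
#' @param condition `"healthy"` or `"halitosis"`.
#' @return named numeric vector of prevalences in [0, 1].
#' @export
otu_prevalence <- function(table, meta, site, condition) {
  stopifnot(site %in% SITES, condition %in% CONDITIONS)
  validate_metadata(table, meta)
  meta <- meta[meta$sample_id %in% colnames(table$counts), , drop = FALSE]
  sel <- meta$sample_id[meta$site == site & meta$condition == condition]
  if (!length(sel)) stop("no samples for ", site, "/", condition)
  rowMeans(table$counts[, sel, drop = FALSE] > 0)
}

#' Classify one OTU into the tiered core-microbiome scheme
#'
#' Labels follow the prevalence rule set of the tongue-coating comparison:
#' `core` when prevalence exceeds 0.75 in both groups, `health_associated`
#' (resp. `halitosis_associated`) when it exceeds 0.75 only in the healthy
#' (resp. halitosis) group, otherwise `none`. Tiers refine a label: tier 1 =
#' prevalence 1.0 in the relevant group(s) with mean relative abundance at
#' or above the abundance threshold; tier 2 = prevalence 1.0 with lower
#' abundance; tier 3 = prevalence above the threshold but below 1.0.
#'
#' @param prev_h,prev_d prevalence in the healthy and halitosis groups.
#' @param mean_ab mean relative abundance (see [core_microbiome()] for the
#'   denominator convention).
#' @param prev_min prevalence threshold (default 0.75, strict).
#' @param ab_min tier-1 abundance threshold (default 0.01).
#' @return list with `label` and `tier` (integer or NA for `none`).
#' @export
classify_core <- function(prev_h, prev_d, mean_ab,
                          prev_min = 0.75, ab_min = 0.01) {
  vals <- c(prev_h, prev_d, mean_ab)
  if (anyNA(vals) || any(vals < 0) || any(c(prev_h, prev_d) > 1))
    stop("prevalences and abundance must lie in [0, 1]")
  in_h <- prev_h > prev_min
  in_d <- prev_d > prev_min
  if (in_h && in_d) {
    label <- "core"; rel_prev <- min(prev_h, prev_d)
  } else if (in_h) {
    label <- "health_associated"; rel_prev <- prev_h
  } else if (in_d) {
    label <- "halitosis_associated"; rel_prev <- prev_d
  } else {
    return(list(label = "none", tier = NA_integer_))
  }
  tier <- if (rel_prev >= 1) {
    if (mean_ab >= ab_min) 1L else 2L
  } else 3L
  list(label = label, tier = tier)
}

#' Tiered core-microbiome classification of tongue-coating OTUs
#'
#' Computes per-OTU prevalence in the healthy and halitosis tongue samples
#' and mean relative abundance, then applies [classify_core()]. For `core`
#' OTUs the abundance denominator is all tongue samples; for associated
#' labels it is the defining group's samples by default
#' (`abundance_scope = "group"`), or all tongue samples with
#' `abundance_scope = "all"`.
#'
#' @param table an [otu_table()].
#' @param meta a [sample_metadata()].
#' @param prev_min,ab_min thresholds passed to [classify_core()].
#' @param abundance_scope `"group"` or `"all"`.
#' @return data.frame, one row per OTU, with prevalences, mean abundance,
#'   `label` and `tier`.
#' @export
core_microbiome <- function(table, meta, prev_min = 0.75, ab_min = 0.01,
                            abundance_scope = c("group", "all")) {
  abundance_scope <- match.arg(abundance_scope)
  prev_h <- otu_prevalence(table, meta, "tongue", "healthy")
  prev_d <- otu_prevalence(table, meta, "tongue", "halitosis")
  meta <- meta[meta$sample_id %in% colnames(table$counts), , drop = FALSE]
  ab <- relative_abundance(table)
  tongue_h <- meta$sample_id[meta$site == "tongue" & meta$condition == "healthy"]
  tongue_d <- meta$sample_id[meta$site == "tongue" & meta$condition == "halitosis"]
  mean_all <- rowMeans(ab[, c(tongue_h, tongue_d), drop = FALSE])
  mean_h <- rowMeans(ab[, tongue_h, drop = FALSE])
  mean_d <- rowMeans(ab[, tongue_d, drop = FALSE])

  ids <- rownames(table$counts)
  label <- character(length(ids)); tier <- integer(length(ids))
  mean_used <- numeric(length(ids))
  for (i in seq_along(ids)) {
    ph <- prev_h[[i]]; pd <- prev_d[[i]]
    # pick the denominator for the abundance criterion before classifying
    m <- if (abundance_scope == "all") mean_all[[i]]
         else if (ph > prev_min && pd > prev_min) mean_all[[i]]
         else if (ph > prev_min) mean_h[[i]]
         else if (pd > prev_min) mean_d[[i]]
         else mean_all[[i]]
    cl <- classify_core(ph, pd, m, prev_min = prev_min, ab_min = ab_min)
    label[i] <- cl$label; tier[i] <- cl$tier; mean_used[i] <- m
  }
  data.frame(otu_id = ids, prev_healthy = unname(prev_h),
             prev_halitosis = unname(prev_d), mean_abundance = mean_used,
             label = label, tier = tier,
             row.names = NULL, stringsAsFactors = FALSE)
}
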