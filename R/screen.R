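#' Maximum fold change of a compound's 16-period series
#'
#' The maximum is taken over observed periods only; missing periods are
#' skipped (they encode "not measured", not zero).
#'
#' @param fc_series Numeric vector of fold-change values (length 16 in a
#'   complete series); `NA` marks an absent period.
#' @return The maximum over present values.
#' @export
compute_fc_max <- function(fc_series) {
  v <- fc_series[!is.na(fc_series)]
  if (length(v) == 0) stop("no fold-change data", call. = FALSE)
  if (any(v < 0)) stop("negative fold change", call. = FALSE)
  max(v)
}

#' Screen compounds on structure, curation class and fold change
#'
#' Applies three removal rules: (1) compounds without structural
#' information are removed (`no_structure`); (2) compounds carrying any
#' tag in `exclusion_tags` - amino acids and derivatives, short
#' aliphatic chains, trivially simple molecules, applied by curation -
#' are removed (`excluded_class`); (3) compounds whose every observed
#' fold-change value is strictly below `threshold` are removed
#' (`low_fc`), i.e. a compound is kept on this rule iff its maximum
#' fold change reaches the threshold.  When several rules apply, the
#' reported reason follows the precedence
#' `no_structure > excluded_class > low_fc`.
#'
#' @param compounds A compound table (see [read_compound_table()]).
#' @param threshold Fold-change threshold (default 2; a value exactly at
#'   the threshold keeps the compound).
#' @param exclusion_tags Character vector of curation tags to remove.
#' @return A list of class `screen_report` with elements `retained`
#'   (character vector of compound ids), `removed` (named character
#'   vector, id -> reason) and `table` (the retained rows of the input).
#' @export
screen_compounds <- function(compounds, threshold = 2,
                             exclusion_tags = character()) {
  stopifnot(threshold > 0)
  compounds <- validate_compound_table(compounds)
  tags <- strsplit(compounds$class_tags, ",", fixed = TRUE)
  tags <- lapply(tags, trimws)
  no_structure <- !nzchar(compounds$structure)
  excluded <- vapply(tags, function(t) any(t %in% exclusion_tags),
                     logical(1))
  low_fc <- !is.na(compounds$fc_max) & compounds$fc_max < threshold
  reason <- rep(NA_character_, nrow(compounds))
  reason[low_fc] <- "low_fc"
  reason[excluded] <- "excluded_class"
  reason[no_structure] <- "no_structure"
  removed <- reason[!is.na(reason)]
  names(removed) <- compounds$compound_id[!is.na(reason)]
  retained <- compounds$compound_id[is.na(reason)]
  structure(list(retained = retained,
                 removed = removed,
                 table = compounds[is.na(reason), , drop = FALSE]),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("screen report: %d retained, %d removed\n",
              length(x$retained), length(x$removed)))
  if (length(x$removed) > 0) {
    print(table(x$removed))
  }
  invisible(x)
}

#' Classify the herb of origin of a compound
#'
#' Compounds are assigned to Radix Astragali (`RA`), Radix Glycyrrhizae
#' (`RG`) or `BOTH` from literature evidence flags.  When literature
#' places a compound in both herbs but quantitative concentration data
#' exist for exactly one of them, the compound is assigned to the herb
#' with concentration data.  Compounds without herb evidence (typically
#' metabolites) are `UNKNOWN`.
#'
#' @param lit_ra,lit_rg Logical literature evidence flags per herb.
#' @param conc_ra,conc_rg Logical concentration-data flags per herb.
#' @return One of `"RA"`, `"RG"`, `"BOTH"`, `"UNKNOWN"` (vectorized).
#' @export
classify_herb_origin <- function(lit_ra, lit_rg,
                                 conc_ra = FALSE, conc_rg = FALSE) {
  n <- max(length(lit_ra), length(lit_rg), length(conc_ra), length(conc_rg))
  lit_ra <- rep_len(as.logical(lit_ra), n)
  lit_rg <- rep_len(as.logical(lit_rg), n)
  conc_ra <- rep_len(as.logical(conc_ra), n)
  conc_rg <- rep_len(as.logical(conc_rg), n)
  out <- rep("UNKNOWN", n)
  out[lit_ra & !lit_rg] <- "RA"
  out[!lit_ra & lit_rg] <- "RG"
  both <- lit_ra & lit_rg
  out[both] <- "BOTH"
  out[both & conc_ra & !conc_rg] <- "RA"
  out[both & !conc_ra & conc_rg] <- "RG"
  out
}

#' Display label of a compound for network coloring
#'
#' Prototype compounds map to `RAC`/`RGC`/`RAGC` according to herb
#' origin; metabolites map to `MC`.
#'
#' @param compounds A compound table.
#' @return Named character vector, compound id -> label.
#' @export
compound_labels <- function(compounds) {
  lab <- ifelse(compounds$compound_class == "metabolite", "MC",
                c(RA = "RAC", RG = "RGC", BOTH = "RAGC",
                  UNKNOWN = "MC")[compounds$herb_origin])
  stats::setNames(unname(lab), compounds$compound_id)
}
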