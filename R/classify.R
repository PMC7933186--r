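#' Stage-resolved expression profiles
#'
#' Builds the per-gene (1-cell, early, late) mean-TPM profile used by the
#' maternal-to-zygotic classifiers, from a condition-mean abundance table.
#'
#' @param table An [abundance_table()] in TPM whose columns are condition
#'   means (see [mean_by_condition()]).
#' @param condition Condition whose stages to extract (default `"control"`).
#' @param assay Assay to extract (default `"rna"`).
#' @return data.frame with columns `gene_id`, `tpm_1cell`, `tpm_early`,
#'   `tpm_late`.
#' @export
stage_profiles <- function(table, condition = "control", assay = "rna") {
  if (table$unit != "TPM") stop("stage profiles require TPM, got ", table$unit)
  pick <- function(stage) {
    keep <- table$samples$assay == assay & table$samples$stage == stage &
      table$samples$condition == condition
    if (!any(keep)) stop("no ", assay, " sample for stage ", stage,
                         ", condition ", condition)
    rowMeans(table$values[, keep, drop = FALSE])
  }
  data.frame(gene_id = rownames(table$values),
             tpm_1cell = unname(pick("one_cell")),
             tpm_early = unname(pick("early")),
             tpm_late = unname(pick("late")),
             stringsAsFactors = FALSE)
}

#' Detect maternally inherited transcripts
#'
#' Maternal mRNAs are those detected in 1-cell embryos: `tpm_1cell > detect`
#' (strict, default 1 TPM).
#'
#' @param profiles Stage-profile data.frame (see [stage_profiles()]).
#' @param detect Detection threshold in TPM.
#' @return Character vector of maternal gene ids.
#' @export
detect_maternal <- function(profiles, detect = 1) {
  profiles$gene_id[profiles$tpm_1cell > detect]
}

#' Classify maternal-to-zygotic kinetics
#'
#' Assigns each gene one of five mutually exclusive classes from its staged
#' mean-TPM profile. Rules are applied in precedence order (first match wins);
#' `fold` (default 2) quantifies "diminished", "stable" and "increase", and
#' `detect` (default 1 TPM, strict on both sides) separates detected from
#' undetectable:
#'
#' 1. `maternal_and_zygotic`: detected in 1-cell embryos and rising at least
#'    `fold`-fold in early or late embryos;
#' 2. `maternal_cleared`: detected in 1-cell embryos, down at least
#'    `fold`-fold by the late stage, and not above the 1-cell level early;
#' 3. `maternal_stable`: detected in 1-cell embryos with early and late
#'    levels within `fold`-fold of the 1-cell level;
#' 4. `newly_zygotic`: undetectable in 1-cell embryos (`tpm_1cell < detect`)
#'    but detected early or late;
#' 5. `unclassified` otherwise (including `tpm_1cell` exactly at `detect`).
#'
#' @param profiles Stage-profile data.frame.
#' @param fold Fold-change threshold (>= 1).
#' @param detect Detection threshold in TPM.
#' @return Factor of classes, aligned with `profiles`.
#' @export
classify_mzt <- function(profiles, fold = 2, detect = 1) {
  stopifnot(fold >= 1)
  p1 <- profiles$tpm_1cell; pe <- profiles$tpm_early; pl <- profiles$tpm_late
  cls <- rep("unclassified", nrow(profiles))
  r1 <- p1 > detect & (pe >= fold * p1 | pl >= fold * p1)
  r2 <- !r1 & p1 > detect & pl <= p1 / fold & pe <= p1
  r3 <- !r1 & !r2 & p1 > detect &
    pe >= p1 / fold & pe <= fold * p1 & pl >= p1 / fold & pl <= fold * p1
  r4 <- p1 < detect & (pe > detect | pl > detect)
  cls[r4] <- "newly_zygotic"
  cls[r3] <- "maternal_stable"
  cls[r2] <- "maternal_cleared"
  cls[r1] <- "maternal_and_zygotic"
  factor(cls, levels = c("maternal_cleared", "maternal_stable",
                         "newly_zygotic", "maternal_and_zygotic",
                         "unclassified"))
}

#' Classify decay timing of maternal transcripts
#'
#' Among maternal genes (`tpm_1cell > detect`), early-degraded mRNAs show at
#' least a `fold`-fold reduction already in early embryos; late-degraded
#' mRNAs are stable (within `fold`-fold) in early embryos but reduced at
#' least `fold`-fold in late embryos; everything else is `neither`.
#' Non-maternal genes are `not_maternal`.
#'
#' @inheritParams classify_mzt
#' @return Factor with levels `early_degraded`, `late_degraded`, `neither`,
#'   `not_maternal`.
#' @export
classify_decay_timing <- function(profiles, fold = 2, detect = 1) {
  stopifnot(fold >= 1)
  p1 <- profiles$tpm_1cell; pe <- profiles$tpm_early; pl <- profiles$tpm_late
  timing <- rep("neither", nrow(profiles))
  early <- pe <= p1 / fold
  late <- !early & pe <= fold * p1 & pl <= p1 / fold
  timing[late] <- "late_degraded"
  timing[early] <- "early_degraded"
  timing[p1 <= detect] <- "not_maternal"
  factor(timing, levels = c("early_degraded", "late_degraded", "neither",
                            "not_maternal"))
}

#' Full gene classification
#'
#' Convenience wrapper returning the stage profile together with both labels.
#'
#' @inheritParams classify_mzt
#' @return data.frame: `gene_id`, the three stage TPMs, `mzt_class`,
#'   `decay_timing`.
#' @export
classify_genes <- function(profiles, fold = 2, detect = 1) {
  profiles$mzt_class <- classify_mzt(profiles, fold, detect)
  profiles$decay_timing <- classify_decay_timing(profiles, fold, detect)
  profiles
}
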