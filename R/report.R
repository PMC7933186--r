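#' End-to-end analysis of a dataset directory
#'
#' Reads every artifact a dataset directory provides (the layout written by
#' [simulate_dataset()]: `genes.bed`, `cds.fa`, `counts_<assay>.tsv`,
#' `samples.tsv`, per-replicate strand-specific IP bedGraphs,
#' `srna_total_mapped.txt`) and runs the full pipeline: TPM/RPM
#' normalization, condition means, target calling with density tiers,
#' maternal-to-zygotic and decay-timing classification, degradation
#' rate/efficiency, fold changes, translational efficiency, CDS/3'UTR
#' partition of antisense 22G coverage, metaprofiles of early- vs
#' late-degraded targets, and codon usage of the two decay sets. Components
#' whose inputs are absent are skipped (and listed in `$missing`).
#'
#' @param dir Dataset directory.
#' @param fold,detect Classifier thresholds (see [classify_mzt()]).
#' @param min_ip_rpm,min_ratio Target-calling thresholds (see
#'   [call_targets()]).
#' @param n_bins Metaprofile bin count.
#' @return A list of class `mzt_analysis`; see the individual components.
#' @export
analyse_dataset <- function(dir, fold = 2, detect = 1, min_ip_rpm = 1,
                            min_ratio = 2, n_bins = 100) {
  path <- function(...) file.path(dir, ...)
  missing <- character(0)
  need <- function(f) {
    ok <- file.exists(path(f))
    if (!ok) missing <<- c(missing, f)
    ok
  }
  if (!need("genes.bed") || !need("samples.tsv"))
    stop("analyse_dataset: missing required input(s): ",
         paste(missing, collapse = ", "))
  genes <- read_bed12(path("genes.bed"))
  out <- list(genes = genes)

  if (need("counts_rna.tsv")) {
    rna <- read_counts(path("counts_rna.tsv"), path("samples.tsv"))
    tpm <- counts_to_tpm(rna, genes)
    mean_tpm <- mean_by_condition(tpm)
    profiles <- stage_profiles(mean_tpm, condition = "control")
    classification <- classify_genes(profiles, fold = fold, detect = detect)
    out$rna <- rna; out$mean_tpm <- mean_tpm
    out$classification <- classification
    out$maternal <- detect_maternal(profiles, detect = detect)
  }

  if (need("counts_srna_ip.tsv") && need("counts_srna_input.tsv")) {
    ip <- read_counts(path("counts_srna_ip.tsv"), path("samples.tsv"))
    input <- read_counts(path("counts_srna_input.tsv"), path("samples.tsv"))
    ip_rpm <- mean_by_condition(counts_to_rpm(ip))
    input_rpm <- mean_by_condition(counts_to_rpm(input))
    out$targets <- call_targets(abundance_vector(ip_rpm, assay = "srna_ip"),
                                abundance_vector(input_rpm, assay = "srna_input"),
                                min_ip_rpm = min_ip_rpm, min_ratio = min_ratio)
  }

  if (!is.null(out$classification)) {
    cl <- out$classification
    rate_of <- function(condition) {
      p <- stage_profiles(out$mean_tpm, condition = condition)
      suppressMessages(degradation_rate(p$tpm_early, p$tpm_1cell))
    }
    have_cond <- unique(out$rna$samples$condition)
    out$degradation <- data.frame(
      gene_id = cl$gene_id,
      mzt_class = cl$mzt_class,
      rate_control = rate_of("control"),
      rate_depleted = if ("csr1_depleted" %in% have_cond)
        rate_of("csr1_depleted") else NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(out$targets))
      out$degradation$tier <- out$targets$tier[
        match(cl$gene_id, out$targets$gene_id)]
    if (all(c("rescue_ADH", "rescue_DDH") %in% have_cond)) {
      adh <- stage_profiles(out$mean_tpm, condition = "rescue_ADH")
      ddh <- stage_profiles(out$mean_tpm, condition = "rescue_DDH")
      out$log2fc_adh_ddh <- data.frame(
        gene_id = adh$gene_id,
        log2fc = log2_fold_change(adh$tpm_early, ddh$tpm_early),
        stringsAsFactors = FALSE)
    }
  }

  if (need("counts_degradome.tsv") && !is.null(out$mean_tpm)) {
    deg <- read_counts(path("counts_degradome.tsv"), path("samples.tsv"))
    deg_tpm <- mean_by_condition(counts_to_tpm(deg, genes))
    de_of <- function(cond) {
      d <- abundance_vector(deg_tpm, assay = "degradome", condition = cond)
      r <- abundance_vector(out$mean_tpm, assay = "rna", stage = "early",
                            condition = cond)
      suppressMessages(degradation_efficiency(d, r))
    }
    conds <- intersect(c("rescue_DDH", "rescue_ADH"),
                       unique(deg$samples$condition))
    out$degradation_efficiency <- data.frame(
      gene_id = rownames(deg$counts),
      stringsAsFactors = FALSE)
    for (cond in conds) out$degradation_efficiency[[cond]] <- de_of(cond)
  }

  if (need("counts_ribo.tsv") && !is.null(out$mean_tpm)) {
    ribo <- read_counts(path("counts_ribo.tsv"), path("samples.tsv"))
    ribo_tpm <- mean_by_condition(counts_to_tpm(ribo, genes))
    rpf <- abundance_vector(ribo_tpm, assay = "ribo")
    rna_early <- abundance_vector(out$mean_tpm, assay = "rna", stage = "early",
                                  condition = "control")
    out$te <- data.frame(gene_id = names(rpf),
                         tpm_rpf = unname(rpf),
                         tpm_rna = unname(rna_early),
                         te = translational_efficiency(rpf, rna_early),
                         stringsAsFactors = FALSE)
  }

  if (need("srna_total_mapped.txt") && need("srna_ip_rep1_plus.bedgraph")) {
    total <- as.numeric(readLines(path("srna_total_mapped.txt"))[1])
    reps <- list(); r <- 1
    while (file.exists(path(sprintf("srna_ip_rep%d_plus.bedgraph", r)))) {
      reps[[r]] <- read_bedgraph_to_tracks(
        path(sprintf("srna_ip_rep%d_plus.bedgraph", r)),
        path(sprintf("srna_ip_rep%d_minus.bedgraph", r)),
        genes, total_mapped = total, orientation = "antisense")
      r <- r + 1
    }
    tracks <- average_track_sets(reps)
    out$tracks <- tracks
    out$region_abundance <- suppressMessages(partition_cds_utr3(tracks, genes))
    if (!is.null(out$classification) && !is.null(out$targets)) {
      cl <- out$classification
      tg <- out$targets$gene_id[out$targets$is_target]
      sets <- list(
        early_degraded = intersect(
          cl$gene_id[cl$decay_timing == "early_degraded"], tg),
        late_degraded = intersect(
          cl$gene_id[cl$decay_timing == "late_degraded"], tg))
      out$metaprofiles <- lapply(names(sets), function(s) {
        ids <- intersect(sets[[s]], names(tracks))
        ids <- ids[vapply(tracks[ids], function(t) length(t$values), 1L) >= n_bins]
        if (length(ids) == 0) return(NULL)
        metaprofile(tracks[ids], n_bins = n_bins, label = s)
      })
      names(out$metaprofiles) <- names(sets)
    }
  }

  if (need("cds.fa") && !is.null(out$classification)) {
    cds <- Biostrings::readDNAStringSet(path("cds.fa"))
    cl <- out$classification
    sets <- list(early_degraded = cl$gene_id[cl$decay_timing == "early_degraded"],
                 late_degraded = cl$gene_id[cl$decay_timing == "late_degraded"])
    out$rscu <- lapply(sets, function(ids) {
      ids <- intersect(ids, names(cds))
      if (length(ids) == 0) return(NULL)
      suppressMessages(rscu(count_codons(cds[ids])))
    })
  }

  out$missing <- missing
  class(out) <- "mzt_analysis"
  out
}

#' @export
print.mzt_analysis <- function(x, ...) {
  cat("<mzt_analysis>\n")
  cat("  components:",
      paste(setdiff(names(x), c("missing")), collapse = ", "), "\n")
  if (length(x$missing))
    cat("  missing inputs:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

write_tsv_out <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  basename(path)
}

group_box_tsv <- function(values, groups, path) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  rows <- lapply(sort(unique(groups)), function(g) {
    b <- box_summary(values[groups == g])
    data.frame(group = g, n = sum(groups == g), q1 = b["q1"],
               median = b["median"], q3 = b["q3"], p5 = b["p5"],
               p95 = b["p95"], row.names = NULL)
  })
  write_tsv_out(do.call(rbind, rows), path)
}

mwu_line <- function(label, x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    return(sprintf("- %s: not computed (empty group)", label))
  mw <- mann_whitney(x, y)
  sprintf("- %s: n = %d vs %d, U = %s, two-tailed MWU p = %s",
          label, mw$n_x, mw$n_y, fmt_num(mw$U), fmt_num(mw$p))
}

#' Write the report bundle
#'
#' Reproduces the analysis' figure logic as a set of TSV tables plus a
#' plain-markdown summary annotated with group sizes and two-tailed
#' Mann-Whitney p-values: class kinetics medians with bootstrap CIs,
#' fold-change and degradation-rate box summaries by 22G-density tier and
#' condition, degradation-efficiency and translational-efficiency summaries,
#' CDS/3'UTR partition, metaprofiles, codon usage, and the enrichment of
#' targets among cleared maternal transcripts. Output is deterministic given
#' `seed` (used only for bootstrap confidence intervals).
#'
#' @param analysis An [analyse_dataset()] result.
#' @param out_dir Output directory.
#' @param seed Integer seed for the bootstrap CIs.
#' @param n_boot Bootstrap resamples for median CIs.
#' @return Invisibly, the paths written.
#' @export
run_report <- function(analysis, out_dir, seed = 1, n_boot = 200) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  lines <- c("# Maternal mRNA clearance report", "")
  if (length(analysis$missing))
    lines <- c(lines, paste("Missing inputs:",
                            paste(analysis$missing, collapse = ", ")), "")
  cl <- analysis$classification
  tg <- analysis$targets

  if (!is.null(cl)) {
    counts <- table(cl$mzt_class)
    lines <- c(lines, "## Transcript classes (control, staged mean TPM)", "",
               sprintf("- maternal detected (1-cell TPM > 1): %d genes",
                       length(analysis$maternal)),
               sprintf("- %s: %d genes", names(counts), as.integer(counts)),
               "")
    # class kinetics: median TPM + bootstrap CI per stage and class
    rows <- list()
    for (g in levels(cl$mzt_class)) {
      sub <- cl[cl$mzt_class == g, ]
      if (nrow(sub) == 0) next
      for (st in c("tpm_1cell", "tpm_early", "tpm_late")) {
        ci <- median_ci(sub[[st]], n_boot = n_boot,
                        seed = seed + nrow(sub) %% 1000)
        rows[[paste(g, st)]] <- data.frame(
          class = g, stage = sub("tpm_", "", st), n = nrow(sub),
          median = ci$median, lo = ci$lo, hi = ci$hi)
      }
    }
    written <- c(written, write_tsv_out(do.call(rbind, rows),
                                        file.path(out_dir, "class_kinetics.tsv")))
    written <- c(written, write_tsv_out(cl, file.path(out_dir,
                                                      "classification.tsv")))
  }

  if (!is.null(tg)) {
    written <- c(written, write_tsv_out(tg, file.path(out_dir, "targets.tsv")))
    lines <- c(lines, "## Argonaute 22G-RNA targets", "",
               sprintf("- targets: %d of %d genes (IP/input >= 2, IP > 1 RPM)",
                       sum(tg$is_target), nrow(tg)),
               sprintf("- tiers: T1 (1-50 RPM] %d, T2 (50-150] %d, T3 (>150) %d",
                       sum(tg$tier == "T1"), sum(tg$tier == "T2"),
                       sum(tg$tier == "T3")), "")
  }

  if (!is.null(analysis$degradation)) {
    d <- analysis$degradation
    cleared <- d[d$mzt_class == "maternal_cleared", ]
    grp <- as.character(cleared$tier)
    grp[is.na(grp) | grp == "none"] <- "non_target"
    written <- c(written, group_box_tsv(
      cleared$rate_control, grp,
      file.path(out_dir, "degradation_rate_by_tier_control.tsv")))
    lines <- c(lines, "## Degradation rate of cleared maternal mRNAs", "",
               mwu_line("T3 vs non-target (control)",
                        cleared$rate_control[grp == "T3"],
                        cleared$rate_control[grp == "non_target"]))
    if (!all(is.na(cleared$rate_depleted))) {
      written <- c(written, group_box_tsv(
        cleared$rate_depleted, grp,
        file.path(out_dir, "degradation_rate_by_tier_depleted.tsv")))
      lines <- c(lines, mwu_line("T3 vs non-target (depleted)",
                                 cleared$rate_depleted[grp == "T3"],
                                 cleared$rate_depleted[grp == "non_target"]))
    }
    lines <- c(lines, "")
  }

  if (!is.null(analysis$log2fc_adh_ddh) && !is.null(tg)) {
    fc <- analysis$log2fc_adh_ddh
    cleared <- analysis$classification$gene_id[
      analysis$classification$mzt_class == "maternal_cleared"]
    sub <- fc[fc$gene_id %in% cleared, ]
    tier <- as.character(tg$tier[match(sub$gene_id, tg$gene_id)])
    tier[tier == "none"] <- "non_target"
    written <- c(written, group_box_tsv(
      sub$log2fc, tier, file.path(out_dir, "log2fc_adh_ddh_by_tier.tsv")))
    is_t <- tier != "non_target"
    lines <- c(lines,
               "## Catalytic-dead vs active rescue (log2FC ADH/DDH, cleared mRNAs)",
               "", mwu_line("targets vs non-targets", sub$log2fc[is_t],
                            sub$log2fc[!is_t]), "")
  }

  if (!is.null(analysis$degradation_efficiency) && !is.null(tg)) {
    de <- analysis$degradation_efficiency
    if (all(c("rescue_ADH", "rescue_DDH") %in% names(de))) {
      tgt <- de$gene_id %in% tg$gene_id[tg$is_target]
      df <- data.frame(
        group = c("targets_DDH", "targets_ADH"),
        n = c(sum(tgt & !is.na(de$rescue_DDH)), sum(tgt & !is.na(de$rescue_ADH))),
        median = c(stats::median(de$rescue_DDH[tgt], na.rm = TRUE),
                   stats::median(de$rescue_ADH[tgt], na.rm = TRUE)))
      written <- c(written, write_tsv_out(
        df, file.path(out_dir, "degradation_efficiency.tsv")))
      lines <- c(lines, "## Degradation efficiency (degradome/RNA)", "",
                 mwu_line("targets ADH vs DDH", de$rescue_ADH[tgt],
                          de$rescue_DDH[tgt]), "")
    }
  }

  if (!is.null(analysis$te) && !is.null(cl)) {
    te <- analysis$te
    timing <- cl$decay_timing[match(te$gene_id, cl$gene_id)]
    keep <- timing %in% c("early_degraded", "late_degraded")
    written <- c(written, group_box_tsv(
      te$te[keep], as.character(timing[keep]),
      file.path(out_dir, "te_by_decay_timing.tsv")))
    lines <- c(lines, "## Translational efficiency", "",
               mwu_line("early- vs late-degraded TE",
                        te$te[timing == "early_degraded"],
                        te$te[timing == "late_degraded"]), "")
  }

  if (!is.null(analysis$metaprofiles)) {
    for (nm in names(analysis$metaprofiles)) {
      mp <- analysis$metaprofiles[[nm]]
      if (is.null(mp)) next
      written <- c(written, write_tsv_out(
        data.frame(bin = seq_len(mp$n_bins), mean_rpm = mp$values,
                   n_genes = mp$n_genes),
        file.path(out_dir, paste0("metaprofile_", nm, ".tsv"))))
    }
  }

  if (!is.null(analysis$region_abundance) && !is.null(cl)) {
    ra <- analysis$region_abundance
    timing <- cl$decay_timing[match(ra$gene_id, cl$gene_id)]
    keep <- timing %in% c("early_degraded", "late_degraded")
    if (any(keep)) {
      long <- rbind(
        data.frame(group = paste0(timing[keep], "_cds"), value = ra$cds_rpm[keep]),
        data.frame(group = paste0(timing[keep], "_utr3"), value = ra$utr3_rpm[keep]))
      written <- c(written, group_box_tsv(
        long$value, long$group, file.path(out_dir, "cds_utr3_22g.tsv")))
    }
  }

  if (!is.null(analysis$rscu)) {
    for (nm in names(analysis$rscu)) {
      if (is.null(analysis$rscu[[nm]])) next
      written <- c(written, write_tsv_out(
        analysis$rscu[[nm]], file.path(out_dir, paste0("rscu_", nm, ".tsv"))))
    }
  }

  if (!is.null(cl) && !is.null(tg)) {
    cleared <- cl$gene_id[cl$mzt_class == "maternal_cleared"]
    targets <- tg$gene_id[tg$is_target]
    ef <- enrichment_factor(length(targets), length(cleared),
                            length(intersect(targets, cleared)),
                            n_genes = nrow(cl))
    written <- c(written, write_tsv_out(
      data.frame(category = "maternal_cleared", observed = ef$observed,
                 predicted = ef$predicted, enrichment = ef$enrichment,
                 n_targets = ef$n_targets, n_category = ef$n_category,
                 n_genes = ef$n_genes),
      file.path(out_dir, "enrichment.tsv")))
    lines <- c(lines, "## Enrichment of targets among cleared maternal mRNAs",
               "",
               sprintf("- observed %d, predicted %s, enrichment %s",
                       ef$observed, fmt_num(ef$predicted),
                       fmt_num(ef$enrichment)), "")
  }

  lines <- c(lines, "## Tables", "", paste0("- ", sort(written)))
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(c(file.path(out_dir, "report.md"), file.path(out_dir, written)))
}
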