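#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults define
#' the study conditions the pipeline is exercised under: 5,000 genes of which
#' 500 are planted Argonaute 22G-RNA targets with an IP/input effect of at
#' least 4, three replicates per library, negative-binomial counts with
#' dispersion 0.05, and class kinetics mirroring staged maternal-transcript
#' decay (see the methods vignette for the rationale behind each value).
#'
#' @param seed Integer root seed (mandatory; all child seeds derive from it
#'   by fixed offsets).
#' @param n_genes Number of genes (>= 10).
#' @param n_targets Number of planted targets.
#' @param replicates Replicates per (assay, stage, condition).
#' @param nb_dispersion Negative-binomial dispersion shared by all counts.
#' @param lib_sizes Named per-assay library sizes.
#' @param class_probs Composition of planted expression classes.
#' @param early_frac_cleared Fraction of cleared genes with the fast (early)
#'   decay archetype.
#' @param target_cleared_frac Fraction of targets drawn from the cleared
#'   class.
#' @param tier_probs Planted tier proportions among targets.
#' @param tier_boost Extra slicing decay factor per tier (active slicer).
#' @param ip_effect_range IP/input enrichment effect range for targets.
#' @param degradome_base Baseline degradome/RNA ratio without slicing.
#' @param cds_density_early,cds_density_late,utr3_density,utr5_density
#'   Antisense 22G coverage densities (RPM per base) by region for the early
#'   (CDS + 3'UTR) and late (3'UTR-only) placement archetypes.
#' @param kinetic_jitter Log-normal SD of per-gene kinetic multipliers.
#' @param n_images Images per condition for the smFISH simulation.
#' @param img_size Image side length (pixels).
#' @param n_spots Named per-condition planted spot counts in the somatic ROI.
#' @param n_spots_germline Spots planted outside the ROI (excluded from
#'   counting).
#' @param spot_amplitude,spot_sigma,noise_sd,background_level Spot rendering
#'   parameters (intensity units and pixels).
#' @param min_spot_sep Minimum center-to-center spot separation (pixels).
#' @param codon_bias Codon-usage bias in [0, 1]; 0 = uniform synonymous
#'   usage.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 5000,
                       n_targets = 500,
                       replicates = 3,
                       nb_dispersion = 0.05,
                       lib_sizes = c(rna = 30e6, gro = 20e6, ribo = 20e6,
                                     degradome = 10e6, srna = 20e6),
                       class_probs = c(maternal_cleared = 0.19,
                                       maternal_stable = 0.15,
                                       newly_zygotic = 0.10,
                                       maternal_and_zygotic = 0.28,
                                       background = 0.28),
                       early_frac_cleared = 0.3,
                       target_cleared_frac = 0.75,
                       tier_probs = c(T1 = 1/3, T2 = 1/3, T3 = 1/3),
                       tier_boost = c(T1 = 1.5, T2 = 2.5, T3 = 4),
                       ip_effect_range = c(4, 8),
                       degradome_base = 0.05,
                       cds_density_early = 1.0,
                       cds_density_late = 0.05,
                       utr3_density = 2.0,
                       utr5_density = 0.1,
                       kinetic_jitter = 0.08,
                       n_images = 10,
                       img_size = 128,
                       n_spots = c(control = 10, csr1_depleted = 30),
                       n_spots_germline = 6,
                       spot_amplitude = 50,
                       spot_sigma = 1.5,
                       noise_sd = 10,
                       background_level = 100,
                       min_spot_sep = 8,
                       codon_bias = 0) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(seed == round(seed), seed < 2^31 - 100,
            n_genes >= 10, n_targets < n_genes, replicates >= 1,
            nb_dispersion >= 0, all(lib_sizes > 0),
            spot_amplitude > 0, noise_sd > 0)
  cfg <- as.list(environment())
  cfg$class_probs <- class_probs / sum(class_probs)
  structure(cfg, class = "sim_config")
}

## child seeds: fixed offsets from the root seed
sim_seed <- function(config, what) {
  off <- c(genes = 11L, truth = 13L, expression = 17L, srna = 19L,
           coverage = 23L, images = 29L)
  as.integer(config$seed + off[[what]])
}

## genomic coordinate of the b-th (0-based) exonic base, genomic-ascending
base_to_genomic <- function(exon_starts, exon_ends, b) {
  w <- exon_ends - exon_starts
  cum <- cumsum(w)
  j <- findInterval(b, c(0, cum), rightmost.closed = FALSE)  # exon index
  exon_starts[j] + (b - c(0, cum)[j])
}

#' Generate gene models and coding sequences
#'
#' Genes have log-uniform spliced lengths in [0.5, 10] kb, 1-4 exons, a short
#' 5'UTR, a CDS occupying most of the transcript and a 3'UTR of 50-500 nt
#' (capped at 30% of the transcript). Coding sequences start with ATG, end
#' with TAA and contain no internal stops; synonymous codon usage is uniform
#' at `codon_bias = 0`. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (named list of [gene_model()]) and `cds`
#'   (a `DNAStringSet`).
#' @export
generate_genes <- function(config) {
  set.seed(sim_seed(config, "genes"))
  n <- config$n_genes
  chroms <- c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX")
  cursor <- stats::setNames(rep(0, length(chroms)), chroms)

  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  pref <- !duplicated(aa)  # first codon per family is the preferred one
  fam_n <- table(aa)[aa]
  w <- (1 - config$codon_bias) + config$codon_bias * ifelse(pref, fam_n, 0)
  w <- as.numeric(w / sum(w))

  genes <- vector("list", n)
  seqs <- character(n)
  ids <- sprintf("gene%04d", seq_len(n))
  for (i in seq_len(n)) {
    L <- round(10 ^ stats::runif(1, log10(500), log10(10000)))
    utr5 <- max(9, round(0.03 * L))
    utr3 <- round(stats::runif(1, 50, min(500, 0.3 * L)))
    cds <- L - utr5 - utr3
    cds <- cds - cds %% 3
    utr3 <- L - utr5 - cds
    k <- sample(1:4, 1)
    cuts <- if (k > 1) sort(sample(seq_len(L - 1), k - 1)) else integer(0)
    widths <- diff(c(0, cuts, L))
    introns <- if (k > 1) sample(50:500, k - 1, replace = TRUE) else integer(0)
    chrom <- chroms[(i - 1) %% length(chroms) + 1]
    g0 <- cursor[chrom]
    exon_starts <- g0 + cumsum(c(0, widths[-k] + introns))
    exon_ends <- exon_starts + widths
    cursor[chrom] <- exon_ends[k] + 200
    strand <- sample(c("+", "-"), 1)
    # CDS occupies transcript [utr5, utr5 + cds); map to genomic thick bounds
    b <- if (strand == "+") c(utr5, utr5 + cds - 1) else
      c(L - utr5 - cds, L - utr5 - 1)
    thick <- c(base_to_genomic(exon_starts, exon_ends, b[1]),
               base_to_genomic(exon_starts, exon_ends, b[2]) + 1)
    genes[[i]] <- gene_model(ids[i], chrom, strand,
                             start = exon_starts[1], end = exon_ends[k],
                             exon_starts = exon_starts, exon_ends = exon_ends,
                             thick_start = thick[1], thick_end = thick[2])
    n_cod <- cds / 3
    body <- sample(sense, n_cod - 2, replace = TRUE, prob = w)
    seqs[i] <- paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  names(genes) <- ids
  cds_set <- Biostrings::DNAStringSet(seqs)
  names(cds_set) <- ids
  list(genes = genes, cds = cds_set)
}

#' Plant the generative truth
#'
#' Assigns each gene an expression class with class-specific stage kinetics,
#' selects target genes with tiers, slicing boosts, IP/input effects,
#' translation levels and antisense 22G placement profiles, and derives the
#' planted class labels by applying the classifier rules to the noise-free
#' expected stage TPM of the slicer-active condition (so planted labels and
#' realized expectations agree by construction).
#'
#' @param config A [sim_config()].
#' @param genes Named list of gene models (for lengths); defaults to
#'   [generate_genes()] output when NULL.
#' @return data.frame (one row per gene) with the planted parameters and
#'   labels.
#' @export
simulate_truth <- function(config, genes = NULL) {
  set.seed(sim_seed(config, "truth"))
  n <- config$n_genes
  ids <- sprintf("gene%04d", seq_len(n))
  arch <- sample(names(config$class_probs), n, replace = TRUE,
                 prob = config$class_probs)
  jit <- function(m) m * exp(stats::rnorm(n, 0, config$kinetic_jitter))
  e1 <- numeric(n); me <- numeric(n); ml <- numeric(n)
  cleared_early <- arch == "maternal_cleared" &
    stats::runif(n) < config$early_frac_cleared
  # maternal baselines are drawn so planted 1-cell values sum to ~1e6, i.e.
  # they already live on the TPM scale the estimator converges to; maternal+
  # zygotic transcripts are deposited modestly (their levels rise later)
  base_mean <- 8.4e5 / n
  for (cls in unique(arch)) {
    idx <- arch == cls
    e1[idx] <- switch(cls,
      maternal_cleared = ,
      maternal_stable = stats::rlnorm(sum(idx), log(base_mean), 1),
      maternal_and_zygotic = stats::rlnorm(sum(idx), log(0.3 * base_mean), 1),
      newly_zygotic = stats::runif(sum(idx), 0.05, 0.5),
      background = stats::runif(sum(idx), 0.1, 0.5))
  }
  me[arch == "maternal_cleared"] <- ifelse(cleared_early[arch == "maternal_cleared"], 0.3, 0.75)
  ml[arch == "maternal_cleared"] <- ifelse(cleared_early[arch == "maternal_cleared"], 0.1, 0.2)
  me[arch == "maternal_stable"] <- 1; ml[arch == "maternal_stable"] <- 1
  me[arch == "maternal_and_zygotic"] <- 0.9
  ml[arch == "maternal_and_zygotic"] <- 3
  me[arch == "newly_zygotic"] <- 0; ml[arch == "newly_zygotic"] <- 0
  me[arch == "background"] <- 1; ml[arch == "background"] <- 1
  me <- jit(me); ml <- jit(ml)
  nz <- arch == "newly_zygotic"

  # targets: mostly cleared maternal genes, inherited at higher levels; the
  # remainder are low-density (T1) targets on translated stable mRNAs, whose
  # 22G-RNAs sit on the 3'UTR only
  is_target <- rep(FALSE, n)
  pool_cleared <- which(arch == "maternal_cleared")
  pool_stable <- which(arch == "maternal_stable")
  n_cl <- min(length(pool_cleared), round(config$n_targets * config$target_cleared_frac))
  t_cleared <- sample(pool_cleared, n_cl)
  t_stable <- sample(pool_stable, config$n_targets - n_cl)
  is_target[c(t_cleared, t_stable)] <- TRUE
  e1[is_target] <- e1[is_target] * 2

  tier <- rep("none", n)
  tier[t_cleared] <- sample(names(config$tier_probs), length(t_cleared),
                            replace = TRUE, prob = config$tier_probs)
  tier[t_stable] <- "T1"
  boost <- rep(1, n)
  boost[is_target] <- config$tier_boost[tier[is_target]]

  # stage expectations; newly-zygotic absolute levels are set by mass
  # balance: zygotic transcription replaces the degraded maternal mass, so
  # each stage's planted total matches the 1-cell total (TPM is
  # compositional -- without this the estimator would rescale every ratio).
  # Zygotic output is condition-independent, so the balance is struck under
  # the active-slicer condition and shared by all conditions.
  ee <- e1 * me; el <- e1 * ml
  ee_act <- ee / boost; el_act <- el / boost
  share <- stats::rlnorm(sum(nz), 0, 1)
  share <- share / sum(share)
  ee_act[nz] <- max(sum(e1) - sum(ee_act), 0.005 * sum(e1)) * share
  el_act[nz] <- max(sum(e1) - sum(el_act), 0.005 * sum(e1)) * share
  ee[nz] <- ee_act[nz]; el[nz] <- el_act[nz]

  # expected stage TPM: slicer-active (control / catalytic rescue) vs
  # inactive (depletion / catalytic-dead rescue). Each stage/condition
  # column is renormalized to 1e6 -- these are the values the TPM estimator
  # converges to, and the planted labels are derived from them so truth and
  # realized expectation agree exactly.
  normcol <- function(v) v / sum(v) * 1e6
  e1 <- normcol(e1)
  ee_active <- normcol(ee_act); el_active <- normcol(el_act)
  ee_inactive <- normcol(ee); el_inactive <- normcol(el)
  lab <- classify_genes(data.frame(gene_id = ids, tpm_1cell = e1,
                                   tpm_early = ee_active,
                                   tpm_late = el_active))

  # 22G abundance: planted IP RPM by tier, effect >= 4; non-target RPMs are
  # rescaled so planted IP RPMs sum to 1e6 (column-sum RPM consistency)
  ip_rpm <- stats::rlnorm(n, log(20), 1.5)
  ip_rpm[is_target] <- c(T1 = NA)  # overwritten below
  rt <- stats::runif(sum(is_target))
  lo <- c(T1 = 5, T2 = 50, T3 = 150)[tier[is_target]]
  hi <- c(T1 = 50, T2 = 150, T3 = 600)[tier[is_target]]
  ip_rpm[is_target] <- lo + rt * (hi - lo)
  free <- 1e6 - sum(ip_rpm[is_target])
  ip_rpm[!is_target] <- ip_rpm[!is_target] * free / sum(ip_rpm[!is_target])
  effect <- rep(1, n)
  effect[is_target] <- stats::runif(sum(is_target), config$ip_effect_range[1],
                                    config$ip_effect_range[2])
  input_rpm <- ip_rpm / effect

  timing <- as.character(lab$decay_timing)
  translation <- stats::runif(n, 0.2, 1)
  translation[is_target & timing == "early_degraded"] <-
    stats::runif(sum(is_target & timing == "early_degraded"), 0.05, 0.3)
  translation[is_target & timing != "early_degraded"] <-
    stats::runif(sum(is_target & timing != "early_degraded"), 0.5, 1)
  placement <- ifelse(!is_target, "none",
                      ifelse(timing == "early_degraded", "cds_and_utr3",
                             "utr3_only"))

  data.frame(gene_id = ids, class_arch = arch,
             mzt_class = as.character(lab$mzt_class),
             decay_timing = timing,
             is_target = is_target, tier = tier, boost = boost,
             e1 = e1, ee_active = ee_active, el_active = el_active,
             ee_inactive = ee_inactive, el_inactive = el_inactive,
             translation = translation, placement = placement,
             ip_rpm = ip_rpm, input_rpm = input_rpm,
             stringsAsFactors = FALSE)
}

slicer_active <- function(condition) {
  condition %in% c("control", "rescue_DDH")
}

nb_draw <- function(mu, dispersion) {
  if (dispersion > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else stats::rpois(length(mu), mu)
}

## one library column: counts with expectation proportional to TPM x length
draw_counts <- function(expected_tpm, len_kb, lib_size, dispersion) {
  mu <- expected_tpm * len_kb
  mu <- mu / sum(mu) * lib_size
  nb_draw(mu, dispersion)
}

#' Simulate staged count tables for RNA, GRO, Ribo and degradome assays
#'
#' Expected TPM follows the planted class kinetics; targets carry an extra
#' slicing decay that is present under the active-slicer conditions (control,
#' catalytically active rescue) and absent under depletion or the
#' catalytic-dead rescue. Nascent (GRO) expectations are identical across
#' conditions; degradome expectation is proportional to RNA level times
#' slicing flux; ribosome-protected fragments are proportional to RNA level
#' times the planted translation level. Counts are negative-binomial with the
#' configured dispersion.
#'
#' @param truth A [simulate_truth()] data.frame.
#' @param config A [sim_config()].
#' @param genes Named list of gene models (for spliced lengths).
#' @return Named list of [count_table()]s: `rna`, `gro`, `ribo`, `degradome`.
#' @export
simulate_expression <- function(truth, config, genes) {
  set.seed(sim_seed(config, "expression"))
  len_kb <- vapply(genes[truth$gene_id], spliced_length, numeric(1)) / 1000
  expected_rna <- function(stage, condition) {
    act <- slicer_active(condition)
    switch(stage,
           one_cell = truth$e1,
           early = if (act) truth$ee_active else truth$ee_inactive,
           late = if (act) truth$el_active else truth$el_inactive)
  }
  build <- function(assay, stages, conditions, expected_fun) {
    cols <- list(); meta <- list()
    for (cond in conditions) for (st in stages)
      for (r in seq_len(config$replicates)) {
        id <- paste(assay, st, cond, paste0("r", r), sep = "_")
        cols[[id]] <- draw_counts(expected_fun(st, cond), len_kb,
                                  config$lib_sizes[[assay]],
                                  config$nb_dispersion)
        meta[[id]] <- data.frame(sample_id = id, assay = assay, stage = st,
                                 condition = cond, replicate = r)
      }
    m <- do.call(cbind, cols)
    rownames(m) <- truth$gene_id
    count_table(m, do.call(rbind, meta))
  }
  rna <- build("rna", c("one_cell", "early", "late"),
               c("control", "csr1_depleted", "rescue_DDH", "rescue_ADH"),
               expected_rna)
  gro <- build("gro", "early", c("control", "csr1_depleted"),
               function(st, cond) truth$ee_inactive)
  ribo <- build("ribo", "early", "control",
                function(st, cond) truth$ee_active * truth$translation)
  degradome <- build("degradome", "early", c("rescue_DDH", "rescue_ADH"),
                     function(st, cond) {
                       flux <- ifelse(truth$is_target & slicer_active(cond),
                                      truth$boost, 1)
                       expected_rna(st, cond) * config$degradome_base * flux
                     })
  list(rna = rna, gro = gro, ribo = ribo, degradome = degradome)
}

#' Simulate 22G-RNA IP/input counts and antisense coverage tracks
#'
#' IP and input gene-level counts follow the planted per-gene RPMs (targets:
#' tiered IP RPM with an IP/input effect of at least the configured minimum;
#' non-targets: equal IP and input expectation). Antisense coverage tracks are
#' generated for target genes from their placement profile: the early
#' archetype covers CDS and 3'UTR, the late archetype the 3'UTR only, with
#' Poisson per-base counts. Track values are raw per-base counts; scale by
#' `1e6 / lib_sizes["srna"]` (or round-trip through bedGraph with that total)
#' to obtain RPM.
#'
#' @inheritParams simulate_expression
#' @return List with `ip`/`input` ([count_table()]s, stage `early`, condition
#'   `control`), `track_reps` (list of per-replicate named track lists, counts
#'   units) and `total_mapped`.
#' @export
simulate_22g <- function(truth, config, genes) {
  set.seed(sim_seed(config, "srna"))
  lib <- config$lib_sizes[["srna"]]
  n <- nrow(truth)
  build <- function(assay, rpm) {
    cols <- list(); meta <- list()
    for (r in seq_len(config$replicates)) {
      id <- paste(assay, "early", "control", paste0("r", r), sep = "_")
      cols[[id]] <- nb_draw(rpm * lib / 1e6, config$nb_dispersion)
      meta[[id]] <- data.frame(sample_id = id, assay = assay, stage = "early",
                               condition = "control", replicate = r)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- truth$gene_id
    count_table(m, do.call(rbind, meta))
  }
  ip <- build("srna_ip", truth$ip_rpm)
  input <- build("srna_input", truth$input_rpm)

  set.seed(sim_seed(config, "coverage"))
  tidx <- which(truth$is_target)
  track_reps <- lapply(seq_len(config$replicates), function(r) {
    trs <- lapply(tidx, function(i) {
      gm <- genes[[truth$gene_id[i]]]
      reg <- tx_regions(gm)
      L <- spliced_length(gm)
      d <- rep(config$utr5_density, L)
      cds_d <- if (truth$placement[i] == "cds_and_utr3")
        config$cds_density_early else config$cds_density_late
      if (!is.null(reg$cds)) d[(reg$cds[1] + 1):reg$cds[2]] <- cds_d
      if (!is.null(reg$utr3)) d[(reg$utr3[1] + 1):reg$utr3[2]] <- config$utr3_density
      coverage_track(gm$gene_id, stats::rpois(L, d * lib / 1e6), "antisense")
    })
    names(trs) <- truth$gene_id[tidx]
    trs
  })
  list(ip = ip, input = input, track_reps = track_reps, total_mapped = lib)
}

#' Simulate single-molecule FISH images
#'
#' Plants 2-D Gaussian spots over Gaussian background noise in synthetic
#' embryo sections. The somatic region of interest is the left two-thirds of
#' the image; the depletion condition plants more ROI spots than control
#' (accumulated, undegraded target mRNA), and a few spots land in the
#' excluded germline region under both conditions. Spots respect a minimum
#' separation (an error is raised if the requested density cannot).
#'
#' @param config A [sim_config()].
#' @return List with `roi` (logical matrix), `images` (list of lists with
#'   `condition`, `pixels`, `truth` data.frame of planted ROI/non-ROI spot
#'   centers).
#' @export
simulate_images <- function(config) {
  set.seed(sim_seed(config, "images"))
  sz <- config$img_size
  roi <- matrix(FALSE, sz, sz)
  roi[, seq_len(round(sz * 2 / 3))] <- TRUE
  margin <- 8
  place <- function(n_roi, n_out) {
    pts <- matrix(numeric(0), 0, 2)
    want <- c(rep(TRUE, n_roi), rep(FALSE, n_out))
    for (inside in want) {
      ok <- FALSE
      for (try in 1:500) {
        y <- sample(seq(margin, sz - margin), 1)
        x <- if (inside) sample(seq(margin, round(sz * 2 / 3) - 3), 1)
        else sample(seq(round(sz * 2 / 3) + 3, sz - margin), 1)
        if (nrow(pts) == 0 ||
            min(sqrt((pts[, 1] - y)^2 + (pts[, 2] - x)^2)) >= config$min_spot_sep) {
          pts <- rbind(pts, c(y, x)); ok <- TRUE; break
        }
      }
      if (!ok) stop("spot density too high for the separation constraint")
    }
    data.frame(y = pts[, 1], x = pts[, 2],
               in_roi = want[seq_len(nrow(pts))])
  }
  render <- function(truth) {
    img <- config$background_level +
      matrix(stats::rnorm(sz * sz, 0, config$noise_sd), sz, sz)
    r <- ceiling(4 * config$spot_sigma)
    for (i in seq_len(nrow(truth))) {
      ys <- max(1, truth$y[i] - r):min(sz, truth$y[i] + r)
      xs <- max(1, truth$x[i] - r):min(sz, truth$x[i] + r)
      g <- outer((ys - truth$y[i])^2, (xs - truth$x[i])^2, "+")
      img[ys, xs] <- img[ys, xs] +
        config$spot_amplitude * exp(-g / (2 * config$spot_sigma^2))
    }
    img
  }
  images <- list()
  for (cond in names(config$n_spots)) {
    for (i in seq_len(config$n_images)) {
      truth <- place(config$n_spots[[cond]], config$n_spots_germline)
      images[[paste(cond, i, sep = "_")]] <-
        list(condition = cond, index = i, pixels = render(truth),
             truth = truth)
    }
  }
  list(roi = roi, images = images)
}

#' Scale coverage tracks by a constant
#'
#' @param tracks Named list of [coverage_track()]s.
#' @param factor Non-negative scalar (e.g. `1e6 / total_mapped` to convert
#'   raw per-base counts to RPM).
#' @return Named list of scaled tracks.
#' @export
scale_tracks <- function(tracks, factor) {
  lapply(tracks, function(t)
    coverage_track(t$gene_id, t$values * factor, t$orientation))
}

#' Simulate a complete dataset on disk
#'
#' Runs the whole generator and writes every artifact as plain text (BED12,
#' FASTA, TSV count tables and sample sheet, strand-specific bedGraph per IP
#' replicate, TIFF images with ROI mask and planted-spot CSV, and the planted
#' truth table). Byte-identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param what Which components to generate (subset of
#'   `c("genes", "expression", "srna", "images")`); truth is always written.
#' @return Invisibly, the list of generated in-memory objects.
#' @export
simulate_dataset <- function(config, out_dir,
                             what = c("genes", "expression", "srna", "images")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gg <- generate_genes(config)
  truth <- simulate_truth(config, gg$genes)
  write_bed12(gg$genes, file.path(out_dir, "genes.bed"))
  Biostrings::writeXStringSet(gg$cds, file.path(out_dir, "cds.fa"))
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- list(genes = gg$genes, cds = gg$cds, truth = truth)
  metas <- list()
  if ("expression" %in% what) {
    expr <- simulate_expression(truth, config, gg$genes)
    for (assay in names(expr)) {
      write_counts(expr[[assay]],
                   file.path(out_dir, paste0("counts_", assay, ".tsv")))
      metas[[assay]] <- expr[[assay]]$samples
    }
    out$expression <- expr
  }
  if ("srna" %in% what) {
    srna <- simulate_22g(truth, config, gg$genes)
    write_counts(srna$ip, file.path(out_dir, "counts_srna_ip.tsv"))
    write_counts(srna$input, file.path(out_dir, "counts_srna_input.tsv"))
    metas$srna_ip <- srna$ip$samples
    metas$srna_input <- srna$input$samples
    for (r in seq_along(srna$track_reps)) {
      tracks_to_bedgraph(srna$track_reps[[r]], gg$genes,
                         file.path(out_dir, sprintf("srna_ip_rep%d_plus.bedgraph", r)),
                         file.path(out_dir, sprintf("srna_ip_rep%d_minus.bedgraph", r)))
    }
    writeLines(as.character(srna$total_mapped),
               file.path(out_dir, "srna_total_mapped.txt"))
    out$srna <- srna
  }
  if (length(metas))
    utils::write.table(do.call(rbind, metas), file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if ("images" %in% what) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    sim <- simulate_images(config)
    tiff::writeTIFF(sim$roi * 1, file.path(img_dir, "roi_mask.tif"),
                    bits.per.sample = 8L)
    truth_rows <- list()
    for (nm in names(sim$images)) {
      im <- sim$images[[nm]]
      tiff::writeTIFF(im$pixels / 1024, file.path(img_dir, paste0(nm, ".tif")),
                      bits.per.sample = 32L)
      truth_rows[[nm]] <- data.frame(image = nm, condition = im$condition,
                                     im$truth)
    }
    utils::write.csv(do.call(rbind, truth_rows),
                     file.path(img_dir, "spots_truth.csv"), row.names = FALSE,
                     quote = FALSE)
    out$images <- sim
  }
  invisible(out)
}
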