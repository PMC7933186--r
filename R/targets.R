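#' Call Argonaute 22G-RNA targets from IP vs input abundance
#'
#' A gene is called a target when the ratio of normalized 22G-RNA abundance in
#' the immunoprecipitate over the input is at least `min_ratio` (default 2)
#' and its IP abundance exceeds `min_ip_rpm` (default 1 RPM, strict). Targets
#' are tiered by IP 22G density: T1 = (1, 50], T2 = (50, 150], T3 = (150, Inf)
#' RPM, so the tiers tile the ">1 / >50 / >150 RPM" labels without overlap.
#' A gene absent from the input but present in the IP gets ratio `Inf`
#' (absence from input cannot disqualify an IP-enriched gene).
#'
#' @param ip,input Named numeric vectors of RPM (typically condition means
#'   across replicates), or single-column/condition-mean [abundance_table()]s
#'   in RPM. Both must cover the same gene universe.
#' @param min_ip_rpm Minimum IP abundance gate (strict `>`), RPM.
#' @param min_ratio Minimum IP/input enrichment ratio (inclusive `>=`).
#' @return data.frame with columns `gene_id`, `ip_rpm`, `input_rpm`,
#'   `enrichment_ratio`, `is_target`, `tier` (factor: none/T1/T2/T3),
#'   ordered by `gene_id`.
#' @export
call_targets <- function(ip, input, min_ip_rpm = 1, min_ratio = 2) {
  ip <- as_rpm_vector(ip, "ip")
  input <- as_rpm_vector(input, "input")
  if (is.null(names(ip)) || is.null(names(input)))
    stop("ip and input must be named by gene_id")
  if (!setequal(names(ip), names(input)))
    stop("ip and input must share the same gene universe")
  ids <- sort(names(ip))
  ip <- ip[ids]; input <- input[ids]
  ratio <- ifelse(input > 0, ip / input, ifelse(ip > 0, Inf, NA_real_))
  is_target <- !is.na(ratio) & ratio >= min_ratio & ip > min_ip_rpm
  tier <- rep("none", length(ids))
  tier[is_target] <- as.character(cut(ip[is_target], c(min_ip_rpm, 50, 150, Inf),
                                      labels = c("T1", "T2", "T3"),
                                      right = TRUE))
  data.frame(gene_id = ids, ip_rpm = unname(ip), input_rpm = unname(input),
             enrichment_ratio = unname(ratio), is_target = unname(is_target),
             tier = factor(tier, levels = c("none", "T1", "T2", "T3")),
             stringsAsFactors = FALSE)
}

as_rpm_vector <- function(x, what) {
  if (inherits(x, "abundance_table")) {
    if (x$unit != "RPM")
      stop(what, " table must be in RPM, got ", x$unit)
    return(rowMeans(x$values))
  }
  if (!is.numeric(x)) stop(what, " must be numeric RPM values")
  x
}

#' Partition antisense 22G abundance into CDS and 3'UTR
#'
#' Sums per-base RPM of antisense coverage tracks over the CDS and 3'UTR of
#' each gene (transcript coordinates). Genes lacking an annotated CDS or
#' 3'UTR are skipped with a message.
#'
#' @param tracks Named list of antisense [coverage_track()]s in RPM.
#' @param genes Named list of [gene_model()] objects.
#' @return data.frame with columns `gene_id`, `cds_rpm`, `utr3_rpm`.
#' @export
partition_cds_utr3 <- function(tracks, genes) {
  rows <- lapply(tracks, function(tr) {
    gm <- genes[[tr$gene_id]]
    if (is.null(gm)) stop("no gene model for track ", tr$gene_id)
    reg <- tx_regions(gm)
    if (is.null(reg$cds) || is.null(reg$utr3)) {
      message("partition_cds_utr3: skipping ", tr$gene_id,
              " (no CDS/3'UTR annotation)")
      return(NULL)
    }
    if (length(tr$values) != spliced_length(gm))
      stop("track length mismatch for gene ", tr$gene_id)
    data.frame(gene_id = tr$gene_id,
               cds_rpm = sum(tr$values[(reg$cds[1] + 1):reg$cds[2]]),
               utr3_rpm = sum(tr$values[(reg$utr3[1] + 1):reg$utr3[2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(0), cds_rpm = numeric(0),
                      utr3_rpm = numeric(0))
  rownames(out) <- NULL
  out
}

#' Overlap between two target sets
#'
#' Counts shared genes and reports the overlap fraction relative to a declared
#' denominator (the union by default, or either set).
#'
#' @param a,b Character vectors of gene ids.
#' @param denominator `"union"`, `"a"` or `"b"`.
#' @return List with `n_a`, `n_b`, `n_overlap`, `denominator`, `fraction`.
#' @export
overlap_target_sets <- function(a, b, denominator = c("union", "a", "b")) {
  denominator <- match.arg(denominator)
  a <- unique(a); b <- unique(b)
  ov <- length(intersect(a, b))
  den <- switch(denominator,
                union = length(union(a, b)),
                a = length(a),
                b = length(b))
  list(n_a = length(a), n_b = length(b), n_overlap = ov,
       denominator = denominator,
       fraction = if (den > 0) ov / den else NA_real_)
}
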