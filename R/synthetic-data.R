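#' Reason codes used by the filters and the generator
#'
#' Each code names the single filter condition a record can be planted to
#' fail. SNV codes correspond to the conditions of [filter_snvs()], INDEL
#' codes to [filter_indels()].
#'
#' @return Named list with elements `snv` and `indel`.
#' @export
filter_reason_codes <- function() {
  list(
    snv = c("call_quality", "tumour_depth", "germline_depth",
            "germline_mismatch", "vaf"),
    indel = c("support_total", "interior_support", "germline_cover",
              "germline_indel_window", "local_mismatch", "vaf",
              "repeat_adjacency")
  )
}

#' Simulation configuration
#'
#' Bundles and validates the knobs of [generate_pair()]. Defaults emulate
#' a diagnostic whole-exome tumour/germline pair at the study's nominal
#' coverage (150x tumour, 50x germline) with a two-clone VAF structure.
#'
#' @param seed Integer master seed; every generator derives its own RNG
#'   stream from it by a fixed offset.
#' @param n_snvs,n_indels Number of SNV / INDEL records to emit
#'   (including planted failures).
#' @param signature_weights Named fractions over reference signature ids,
#'   summing to 1; contexts of generated SNVs are drawn from this mixture.
#' @param clone_vafs_diagnostic,clone_vafs_residual Per-clone expected
#'   variant allele fractions, each in (0, 1].
#' @param planted_failures_snv,planted_failures_indel Named integer
#'   counts of records to plant that fail exactly one filter condition;
#'   names must be reason codes from [filter_reason_codes()].
#' @param mean_tumour_depth,mean_germline_depth Poisson means for read
#'   depths.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_snvs = 200L,
                              n_indels = 40L,
                              signature_weights = c(Sig1 = 1),
                              clone_vafs_diagnostic = c(0.45, 0.25),
                              clone_vafs_residual = c(0.45, 0.12),
                              planted_failures_snv = integer(0),
                              planted_failures_indel = integer(0),
                              mean_tumour_depth = 150,
                              mean_germline_depth = 50) {
  stopifnot(n_snvs >= 0, n_indels >= 0,
            mean_tumour_depth > 0, mean_germline_depth > 0)
  if (abs(sum(signature_weights) - 1) > 1e-9) {
    stop("signature_weights must sum to 1 (got ", sum(signature_weights), ")")
  }
  if (is.null(names(signature_weights)) || any(!nzchar(names(signature_weights)))) {
    stop("signature_weights must be named by signature id")
  }
  if (any(signature_weights < 0)) stop("signature_weights must be nonnegative")
  for (v in list(clone_vafs_diagnostic, clone_vafs_residual)) {
    if (length(v) > 0 && (any(v <= 0) || any(v > 1))) stop("clone VAFs must lie in (0, 1]")
  }
  codes <- filter_reason_codes()
  check_planted <- function(pf, known, label, n_total) {
    pf <- pf[pf > 0]
    unknown <- setdiff(names(pf), known)
    if (length(unknown) > 0) {
      stop("unknown ", label, " reason-code(s): ", paste(unknown, collapse = ", "))
    }
    if (sum(pf) > n_total) {
      stop("planted ", label, " failures (", sum(pf), ") exceed the record count (", n_total, ")")
    }
    pf
  }
  planted_failures_snv <- check_planted(planted_failures_snv, codes$snv, "SNV", n_snvs)
  planted_failures_indel <- check_planted(planted_failures_indel, codes$indel, "INDEL", n_indels)
  structure(
    list(
      seed = as.integer(seed), n_snvs = as.integer(n_snvs),
      n_indels = as.integer(n_indels),
      signature_weights = signature_weights,
      clone_vafs_diagnostic = clone_vafs_diagnostic,
      clone_vafs_residual = clone_vafs_residual,
      planted_failures_snv = planted_failures_snv,
      planted_failures_indel = planted_failures_indel,
      mean_tumour_depth = mean_tumour_depth,
      mean_germline_depth = mean_germline_depth
    ),
    class = "simulation_config"
  )
}

# gene pool used by the generator; a mix of breast-cancer genes and fillers
generator_gene_pool <- function() {
  c("TP53", "PIK3CA", "ARID1A", "ARID1B", "ATM", "ATR", "BRCA1", "BRCA2",
    "CHEK2", "PTEN", "PALB2", "RAD51C", "NOTCH1", "MED12", "VAV3", "MDM4",
    "NCOR1", "FOXA1", "MYC", "GATA3",
    sprintf("GENE%03d", 1:60))
}

new_variant_frame <- function(n) {
  df <- data.frame(
    record_id = character(n), sample_id = character(n),
    chrom = character(n), pos = numeric(n),
    ref = character(n), alt = character(n), kind = character(n),
    call_quality = numeric(n), tumour_depth = numeric(n),
    tumour_alt_reads = numeric(n), vaf = numeric(n),
    germline_depth = numeric(n), germline_mismatch_fraction = numeric(n),
    consequence = character(n), gene = character(n), context = character(n),
    stringsAsFactors = FALSE
  )
  for (pn in predictor_names()) df[[pn]] <- character(n)
  df$indel_support_total <- numeric(n)
  df$indel_support_interior <- numeric(n)
  df$germline_cover_at_site <- numeric(n)
  df$germline_indels_within_20bp <- numeric(n)
  df$local_mismatch_rate_10bp <- numeric(n)
  df$adjacent_repeat_regions <- numeric(n)
  df
}

class_to_snv <- function(cls) {
  # "A[C>T]G" -> ref C, alt T, context "ACG"
  list(
    ref = substr(cls, 3, 3),
    alt = substr(cls, 5, 5),
    context = paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7))
  )
}

draw_consequences <- function(n) {
  sample(
    consequence_levels(), n, replace = TRUE,
    prob = c(0.35, 0.05, 0.05, 0.20, 0.15, 0.10, 0.10)
  )
}

draw_verdicts <- function(n) {
  sample(c("deleterious", "tolerated", "unknown"), n, replace = TRUE,
         prob = c(0.3, 0.5, 0.2))
}

#' Generate a synthetic tumour/germline variant pair with ground truth
#'
#' Emits a tumour variant table in the schema of [variant_columns()], a
#' small germline polymorphism table, and a ground-truth table recording
#' each tumour record's intended filter fate (pass, or fail with exactly
#' one reason code), its generating signature, and its clone.
#'
#' Records intended to pass satisfy every filter threshold with a margin
#' of at least one unit (1 read/quality point for integer thresholds,
#' 0.01 for fractions). Planted failures fail exactly their planted
#' condition. Trinucleotide contexts of SNVs are drawn from the signature
#' mixture given by `config$signature_weights` over the rows of
#' `signatures`; alt read counts are binomial draws at the record's clone
#' VAF and depth (clamped where needed to preserve the intended fate).
#' Depths are Poisson around the configured means.
#'
#' @param config A [simulation_config()].
#' @param signatures Reference `signature_matrix`; defaults to
#'   [synthetic_signatures()]. Must contain every id named in
#'   `config$signature_weights`.
#' @param sample_id Sample id stamped on the records.
#' @return List with elements `tumour`, `germline` (variant data.frames)
#'   and `truth` (data.frame: `record_id`, `kind`, `intended_fate`,
#'   `reason`, `signature`, `clone`).
#' @export
generate_pair <- function(config, signatures = synthetic_signatures(),
                          sample_id = "S1") {
  stopifnot(inherits(config, "simulation_config"))
  signatures <- as_signature_matrix(signatures)
  missing_sigs <- setdiff(names(config$signature_weights), rownames(signatures))
  if (length(missing_sigs) > 0) {
    stop("signature_weights name signatures absent from the matrix: ",
         paste(missing_sigs, collapse = ", "))
  }
  tum_snv <- with_stream(config$seed, 11L, generate_snvs(config, signatures, sample_id))
  tum_indel <- with_stream(config$seed, 12L, generate_indels(config, sample_id))
  germline <- with_stream(config$seed, 13L, generate_germline(config, sample_id))
  tumour <- rbind(tum_snv$records, tum_indel$records)
  truth <- rbind(tum_snv$truth, tum_indel$truth)
  rownames(tumour) <- rownames(truth) <- NULL
  list(tumour = tumour, germline = germline, truth = truth, config = config)
}

generate_snvs <- function(config, signatures, sample_id) {
  n <- config$n_snvs
  df <- new_variant_frame(n)
  truth <- data.frame(
    record_id = character(n), kind = rep("SNV", n),
    intended_fate = rep("pass", n), reason = rep("", n),
    signature = character(n), clone = integer(n), stringsAsFactors = FALSE
  )
  if (n == 0) return(list(records = df, truth = truth[0, ]))

  pf <- config$planted_failures_snv
  fail_reason <- rep("", n)
  if (length(pf) > 0) fail_reason[seq_len(sum(pf))] <- rep(names(pf), pf)

  w <- config$signature_weights
  sig_idx <- sample(names(w), n, replace = TRUE, prob = w)
  cls_idx <- vapply(sig_idx, function(s) sample.int(96, 1, prob = signatures[s, ]), 1L)
  cls <- sbs_classes()[cls_idx]
  parts <- class_to_snv(cls)

  clones <- config$clone_vafs_diagnostic
  clone_id <- if (length(clones) > 0) sample.int(length(clones), n, replace = TRUE) else rep(1L, n)
  clone_vaf <- if (length(clones) > 0) clones[clone_id] else rep(0.4, n)

  depth <- pmax(51, stats::rpois(n, config$mean_tumour_depth))
  quality <- round(stats::runif(n, 13, 60), 1)
  gdepth <- pmax(21, stats::rpois(n, config$mean_germline_depth))
  gmm <- round(stats::runif(n, 0, 0.09), 4)

  # planted single-condition failures
  f <- fail_reason
  quality[f == "call_quality"] <- round(stats::runif(sum(f == "call_quality"), 1, 10.9), 1)
  depth[f == "tumour_depth"] <- sample(49, sum(f == "tumour_depth"), replace = TRUE)
  gdepth[f == "germline_depth"] <- sample(19, sum(f == "germline_depth"), replace = TRUE)
  gmm[f == "germline_mismatch"] <- round(stats::runif(sum(f == "germline_mismatch"), 0.11, 0.5), 4)

  alt <- stats::rbinom(n, depth, clone_vaf)
  # clamp so that intended-pass records clear the VAF threshold with margin
  lo <- ceiling(0.11 * depth)
  alt <- pmax(alt, lo)
  alt <- pmin(alt, depth)
  low <- f == "vaf"
  if (any(low)) {
    cap <- pmax(1, floor(0.09 * depth[low]))
    alt[low] <- vapply(cap, function(k) sample.int(k, 1), 1L)
  }

  df$record_id <- sprintf("%s_SNV%05d", sample_id, seq_len(n))
  df$sample_id <- sample_id
  df$chrom <- paste0("chr", sample(22, n, replace = TRUE))
  df$pos <- sample(1e6, n, replace = TRUE) + seq_len(n) * 1e6
  df$ref <- parts$ref
  df$alt <- parts$alt
  df$kind <- "SNV"
  df$call_quality <- quality
  df$tumour_depth <- depth
  df$tumour_alt_reads <- alt
  df$vaf <- alt / depth
  df$germline_depth <- gdepth
  df$germline_mismatch_fraction <- gmm
  df$consequence <- draw_consequences(n)
  df$gene <- ifelse(df$consequence == "intergenic", "",
                    sample(generator_gene_pool(), n, replace = TRUE))
  df$context <- parts$context
  for (pn in predictor_names()) df[[pn]] <- draw_verdicts(n)

  truth$record_id <- df$record_id
  truth$intended_fate <- ifelse(f == "", "pass", "fail")
  truth$reason <- f
  truth$signature <- sig_idx
  truth$clone <- clone_id
  list(records = df, truth = truth)
}

generate_indels <- function(config, sample_id) {
  n <- config$n_indels
  df <- new_variant_frame(n)
  truth <- data.frame(
    record_id = character(n), kind = character(n),
    intended_fate = rep("pass", n), reason = rep("", n),
    signature = rep("", n), clone = integer(n), stringsAsFactors = FALSE
  )
  if (n == 0) return(list(records = df, truth = truth[0, ]))

  pf <- config$planted_failures_indel
  f <- rep("", n)
  if (length(pf) > 0) f[seq_len(sum(pf))] <- rep(names(pf), pf)

  clones <- config$clone_vafs_diagnostic
  clone_id <- if (length(clones) > 0) sample.int(length(clones), n, replace = TRUE) else rep(1L, n)
  clone_vaf <- if (length(clones) > 0) clones[clone_id] else rep(0.4, n)

  depth <- pmax(51, stats::rpois(n, config$mean_tumour_depth))
  support <- pmax(21, stats::rpois(n, 40))
  interior <- pmax(6, round(support * stats::runif(n, 0.3, 0.6)))
  gcover <- pmax(21, stats::rpois(n, config$mean_germline_depth))
  gwin <- rep(0, n)
  lmm <- round(stats::runif(n, 0, 0.09), 4)
  repeats <- sample(0:4, n, replace = TRUE)

  # support_total failures stay >= 6 so interior support (<= total) can
  # still pass with margin
  support[f == "support_total"] <- sample(6:19, sum(f == "support_total"), replace = TRUE)
  interior[f == "interior_support"] <- sample(0:4, sum(f == "interior_support"), replace = TRUE)
  gcover[f == "germline_cover"] <- sample(19, sum(f == "germline_cover"), replace = TRUE)
  gwin[f == "germline_indel_window"] <- sample(3, sum(f == "germline_indel_window"), replace = TRUE)
  lmm[f == "local_mismatch"] <- round(stats::runif(sum(f == "local_mismatch"), 0.11, 0.4), 4)
  repeats[f == "repeat_adjacency"] <- sample(6:12, sum(f == "repeat_adjacency"), replace = TRUE)

  alt <- stats::rbinom(n, depth, clone_vaf)
  alt <- pmin(pmax(alt, ceiling(0.11 * depth)), depth)
  low <- f == "vaf"
  if (any(low)) {
    cap <- pmax(1, floor(0.09 * depth[low]))
    alt[low] <- vapply(cap, function(k) sample.int(k, 1), 1L)
  }

  ins <- sample(c(TRUE, FALSE), n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  anchor <- sample(bases, n, replace = TRUE)
  extra <- sample(bases, n, replace = TRUE)

  df$record_id <- sprintf("%s_IND%05d", sample_id, seq_len(n))
  df$sample_id <- sample_id
  df$chrom <- paste0("chr", sample(22, n, replace = TRUE))
  df$pos <- sample(1e6, n, replace = TRUE) + seq_len(n) * 1e6
  df$ref <- ifelse(ins, anchor, paste0(anchor, extra))
  df$alt <- ifelse(ins, paste0(anchor, extra), anchor)
  df$kind <- ifelse(ins, "INS", "DEL")
  df$call_quality <- round(stats::runif(n, 13, 60), 1)
  df$tumour_depth <- depth
  df$tumour_alt_reads <- alt
  df$vaf <- alt / depth
  df$germline_depth <- pmax(21, stats::rpois(n, config$mean_germline_depth))
  df$germline_mismatch_fraction <- round(stats::runif(n, 0, 0.09), 4)
  df$consequence <- draw_consequences(n)
  df$gene <- ifelse(df$consequence == "intergenic", "",
                    sample(generator_gene_pool(), n, replace = TRUE))
  df$context <- ""
  for (pn in predictor_names()) df[[pn]] <- "unknown"
  df$indel_support_total <- support
  df$indel_support_interior <- pmin(interior, support)
  df$germline_cover_at_site <- gcover
  df$germline_indels_within_20bp <- gwin
  df$local_mismatch_rate_10bp <- lmm
  df$adjacent_repeat_regions <- repeats

  truth$record_id <- df$record_id
  truth$kind <- df$kind
  truth$intended_fate <- ifelse(f == "", "pass", "fail")
  truth$reason <- f
  truth$clone <- clone_id
  list(records = df, truth = truth)
}

generate_germline <- function(config, sample_id) {
  n <- 25L
  df <- new_variant_frame(n)
  bases <- c("A", "C", "G", "T")
  cls <- sbs_classes()[sample(96, n, replace = TRUE)]
  parts <- class_to_snv(cls)
  depth <- pmax(21, stats::rpois(n, config$mean_germline_depth))
  alt <- pmax(1, stats::rbinom(n, depth, 0.5))
  df$record_id <- sprintf("%s_G%04d", sample_id, seq_len(n))
  df$sample_id <- paste0(sample_id, "_germline")
  df$chrom <- paste0("chr", sample(22, n, replace = TRUE))
  df$pos <- sample(1e6, n, replace = TRUE) + seq_len(n) * 1e6
  df$ref <- parts$ref
  df$alt <- parts$alt
  df$kind <- "SNV"
  df$call_quality <- round(stats::runif(n, 20, 60), 1)
  df$tumour_depth <- depth
  df$tumour_alt_reads <- pmin(alt, depth)
  df$vaf <- df$tumour_alt_reads / depth
  df$germline_depth <- depth
  df$germline_mismatch_fraction <- 0
  df$consequence <- draw_consequences(n)
  df$gene <- sample(generator_gene_pool(), n, replace = TRUE)
  df$context <- parts$context
  for (pn in predictor_names()) df[[pn]] <- "unknown"
  df
}

#' Generate a per-base depth track with a known callable fraction
#'
#' Produces a run-compressed depth track (see [read_depth_track()] for
#' the on-disk format) over `length_bp` positions on a single contig in
#' which exactly `round(length_bp * callable_fraction)` positions have
#' depth >= 20. Callable positions get depths of 20 plus a Poisson(15)
#' excess; uncallable positions get depths drawn below 20.
#'
#' @param length_bp Track length (> 0).
#' @param callable_fraction Target fraction of positions at depth >= 20.
#' @param seed Integer seed.
#' @return Depth-track data.frame (`chrom`, `start`, `end`, `depth`),
#'   0-based half-open intervals.
#' @export
generate_depth_track <- function(length_bp, callable_fraction, seed = 1L) {
  if (length_bp <= 0) stop("length_bp must be positive")
  stopifnot(callable_fraction >= 0, callable_fraction <= 1)
  with_stream(seed, 21L, {
    n_call <- round(length_bp * callable_fraction)
    depth <- integer(length_bp)
    callable_pos <- sample.int(length_bp, n_call)
    depth[callable_pos] <- 20L + stats::rpois(n_call, 15)
    rest <- setdiff(seq_len(length_bp), callable_pos)
    depth[rest] <- pmin(stats::rpois(length(rest), 10), 19L)
    r <- rle(depth)
    ends <- cumsum(r$lengths)
    data.frame(
      chrom = "chr1", start = c(0, ends[-length(ends)]), end = ends,
      depth = r$values
    )
  })
}

#' Expand a run-compressed depth track to per-base depths
#'
#' @param track Depth-track data.frame.
#' @return Integer vector of per-base depths (all contigs concatenated).
#' @export
depth_vector <- function(track) {
  assert_columns(track, c("chrom", "start", "end", "depth"), "depth track")
  rep(track$depth, track$end - track$start)
}
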