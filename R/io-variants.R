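#' Variant table schema
#'
#' Somatic calls are carried as a plain data.frame with one row per
#' variant and a fixed, documented column order (stable diffs on disk).
#' Columns:
#'
#' * `record_id` — unique id within a table.
#' * `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`.
#' * `kind` — `"SNV"`, `"INS"` or `"DEL"`.
#' * `call_quality` — the caller's phred-like q-value.
#' * `tumour_depth`, `tumour_alt_reads`, `vaf` — tumour-sample evidence;
#'   `vaf` is a fraction in \[0, 1\] and must agree with
#'   `tumour_alt_reads / tumour_depth` within 0.005 when depth > 0.
#' * `germline_depth`, `germline_mismatch_fraction` — matched-normal
#'   evidence at the site (the mismatch fraction is ingested precomputed).
#' * `consequence` — one of missense, stop_gained, splice_site,
#'   synonymous, intronic, intergenic, other.
#' * `gene` — symbol or `""`.
#' * `context` — pyrimidine-normalized trinucleotide (middle base C or T)
#'   for SNVs, `""` otherwise.
#' * six predictor verdict columns (`sift`, `polyphen`, `provean`,
#'   `mutation_taster`, `mutation_assessor`, `lrt`), each
#'   deleterious/tolerated/unknown.
#' * INDEL read geometry: `indel_support_total`, `indel_support_interior`
#'   (support with the INDEL at least 25 bp from both read ends),
#'   `germline_cover_at_site`, `germline_indels_within_20bp`,
#'   `local_mismatch_rate_10bp`, `adjacent_repeat_regions`.
#'
#' @return Character vector with the canonical column order.
#' @export
variant_columns <- function() {
  c(
    "record_id", "sample_id", "chrom", "pos", "ref", "alt", "kind",
    "call_quality", "tumour_depth", "tumour_alt_reads", "vaf",
    "germline_depth", "germline_mismatch_fraction",
    "consequence", "gene", "context",
    predictor_names(),
    "indel_support_total", "indel_support_interior",
    "germline_cover_at_site", "germline_indels_within_20bp",
    "local_mismatch_rate_10bp", "adjacent_repeat_regions"
  )
}

consequence_levels <- function() {
  c("missense", "stop_gained", "splice_site", "synonymous", "intronic",
    "intergenic", "other")
}

# Per-row invariant check; returns a character vector of problems ("" = ok).
variant_row_problems <- function(df) {
  p <- character(nrow(df))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    p[bad & p == ""] <<- msg
  }
  flag(!df$kind %in% c("SNV", "INS", "DEL"), "unknown kind")
  flag(df$tumour_alt_reads > df$tumour_depth, "tumour_alt_reads > tumour_depth")
  flag(df$vaf < 0 | df$vaf > 1, "vaf outside [0, 1]")
  hasdp <- !is.na(df$tumour_depth) & df$tumour_depth > 0
  dev <- abs(df$vaf - df$tumour_alt_reads / df$tumour_depth)
  flag(hasdp & dev > 0.005, "vaf disagrees with alt/depth")
  snv <- df$kind == "SNV"
  ctx_ok <- nchar(df$context) == 3 & substr(df$context, 2, 2) %in% c("C", "T")
  flag(snv & !ctx_ok, "SNV context not a pyrimidine-centred 3-mer")
  flag(!df$consequence %in% consequence_levels(), "unknown consequence")
  for (pn in predictor_names()) {
    flag(!df[[pn]] %in% c("deleterious", "tolerated", "unknown"),
         paste0("invalid ", pn, " verdict"))
  }
  p
}

validate_variants <- function(df, what = "variant table") {
  assert_columns(df, variant_columns(), what)
  df <- df[, variant_columns()]
  problems <- variant_row_problems(df)
  bad <- problems != ""
  if (any(bad)) {
    warning(
      sum(bad), " row(s) of ", what, " violated invariants and were dropped ",
      "(first: row ", which(bad)[1], ", ", problems[which(bad)[1]], ")"
    )
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read a somatic variant table
#'
#' Two dialects are supported. `"maf_tsv"` is the package's MAF-like
#' tab-separated table with the exact header of [variant_columns()]
#' (unknown extra columns are preserved and re-emitted by
#' [write_variants()]). `"vcf_minimal"` is a minimal VCF 4.x subset
#' (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT + one sample with DP and
#' AD); fields the VCF cannot carry (consequence, predictor verdicts,
#' INDEL geometry) are filled with neutral defaults. Rows violating the
#' schema invariants are dropped with a counted warning.
#'
#' @param path File path.
#' @param dialect `"maf_tsv"` (default) or `"vcf_minimal"`.
#' @param sample_id Sample id used for the VCF dialect (defaults to the
#'   VCF sample column name).
#' @return Validated variant data.frame; the number of dropped rows is in
#'   `attr(, "n_rejected")`.
#' @export
read_variants <- function(path, dialect = c("maf_tsv", "vcf_minimal"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "maf_tsv") {
    df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
    df <- coerce_variant_types(df, path)
    extra <- setdiff(names(df), variant_columns())
    problems <- variant_row_problems(df[, variant_columns()])
    bad <- problems != ""
    if (any(bad)) {
      warning(
        sum(bad), " row(s) of '", basename(path), "' violated invariants and ",
        "were dropped (first: row ", which(bad)[1], ", ", problems[which(bad)[1]], ")"
      )
    }
    out <- df[!bad, c(variant_columns(), extra), drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_rejected") <- sum(bad)
    out
  } else {
    read_variants_vcf(path, sample_id)
  }
}

coerce_variant_types <- function(df, path) {
  assert_columns(df, variant_columns(), paste0("'", basename(path), "'"))
  num <- c("pos", "call_quality", "tumour_depth", "tumour_alt_reads", "vaf",
           "germline_depth", "germline_mismatch_fraction",
           "indel_support_total", "indel_support_interior",
           "germline_cover_at_site", "germline_indels_within_20bp",
           "local_mismatch_rate_10bp", "adjacent_repeat_regions")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "")) {
      stop("malformed numeric value in column '", cn, "' of ", path,
           " (line ", which(is.na(v))[1] + 1L, ")")
    }
    df[[cn]] <- v
  }
  df
}

read_variants_vcf <- function(path, sample_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcf_minimal dialect requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- as.numeric(vcfR::extract.gt(v, element = "DP")[, 1])
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  adm <- do.call(rbind, lapply(strsplit(ad, ","), as.numeric))
  alt_reads <- adm[, 2]
  sid <- sample_id %||% colnames(v@gt)[2]
  kind <- ifelse(
    nchar(fix$REF) == nchar(fix$ALT) & nchar(fix$REF) == 1, "SNV",
    ifelse(nchar(fix$ALT) > nchar(fix$REF), "INS", "DEL")
  )
  n <- nrow(fix)
  df <- data.frame(
    record_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                       paste0(sid, ":", fix$CHROM, ":", fix$POS, ":", fix$REF, ">", fix$ALT),
                       fix$ID),
    sample_id = sid, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, kind = kind,
    call_quality = as.numeric(fix$QUAL),
    tumour_depth = dp, tumour_alt_reads = alt_reads,
    vaf = ifelse(dp > 0, alt_reads / dp, 0),
    germline_depth = NA_real_, germline_mismatch_fraction = NA_real_,
    consequence = "other", gene = "",
    context = "", stringsAsFactors = FALSE
  )
  # the VCF subset carries no annotation; neutral defaults
  for (pn in predictor_names()) df[[pn]] <- "unknown"
  df$indel_support_total <- ifelse(kind == "SNV", 0, alt_reads)
  df$indel_support_interior <- 0
  df$germline_cover_at_site <- 0
  df$germline_indels_within_20bp <- 0
  df$local_mismatch_rate_10bp <- 0
  df$adjacent_repeat_regions <- 0
  ctx <- rep("", n)
  info_ctx <- vcfR::extract.info(v, element = "CTX")
  if (!all(is.na(info_ctx))) ctx[!is.na(info_ctx)] <- info_ctx[!is.na(info_ctx)]
  df$context <- ctx
  # germline evidence via INFO keys if present
  gdp <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "GDP")))
  gmm <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "GMM")))
  if (!all(is.na(gdp))) df$germline_depth <- gdp
  if (!all(is.na(gmm))) df$germline_mismatch_fraction <- gmm
  df$germline_depth[is.na(df$germline_depth)] <- 0
  df$germline_mismatch_fraction[is.na(df$germline_mismatch_fraction)] <- 0
  validate_variants(df, paste0("'", basename(path), "'"))
}

#' Write a somatic variant table (MAF-like TSV)
#'
#' Emits the fixed column order of [variant_columns()]; a read/write
#' round-trip through [read_variants()] is byte-identical for tables that
#' satisfy the schema.
#'
#' @param records Variant data.frame.
#' @param path Output path.
#' @export
write_variants <- function(records, path) {
  assert_columns(records, variant_columns(), "records")
  extra <- setdiff(names(records), variant_columns())
  out <- records[, c(variant_columns(), extra)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-base depth track
#'
#' The on-disk format is a BED-like 4-column TSV (`chrom`, `start`, `end`,
#' `depth`) with 0-based half-open intervals, one depth per run of equal
#' coverage. In memory the track is a data.frame with those columns.
#'
#' @param path File path.
#' @return For `read_depth_track`, a depth-track data.frame.
#' @export
read_depth_track <- function(path) {
  df <- utils::read.table(
    path, sep = "\t", col.names = c("chrom", "start", "end", "depth"),
    colClasses = c("character", "numeric", "numeric", "numeric")
  )
  if (any(df$end <= df$start)) stop("depth track has empty or inverted intervals")
  df
}

#' @param track Depth-track data.frame.
#' @rdname read_depth_track
#' @export
write_depth_track <- function(track, path) {
  assert_columns(track, c("chrom", "start", "end", "depth"), "depth track")
  utils::write.table(
    track[, c("chrom", "start", "end", "depth")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read / write gene-set collections (GMT)
#'
#' Standard tab-separated GMT: set name, description, then gene symbols.
#' Symbols are uppercased and de-duplicated within each set; duplicate
#' set names are an error. The background universe defaults to the union
#' of all set members.
#'
#' @param path File path.
#' @return For `read_gmt`, a `gene_set_collection`: a named list of
#'   character vectors with attributes `descriptions` and `universe_size`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) stop("duplicate gene set name: ", dup[1])
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- nm
  if (any(lengths(sets) == 0)) stop("empty gene set: ", nm[lengths(sets) == 0][1])
  as_gene_sets(sets, vapply(parts, `[[`, "", 2))
}

#' Construct a gene-set collection from a named list
#'
#' Uppercases and de-duplicates each set and attaches the background
#' universe size (distinct genes across all sets).
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional per-set description strings.
#' @return A `gene_set_collection`.
#' @export
as_gene_sets <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, function(g) unique(toupper(g)))
  structure(
    sets,
    descriptions = descriptions %||% rep("", length(sets)),
    universe_size = length(unique(unlist(sets))),
    class = "gene_set_collection"
  )
}

#' @param sets A `gene_set_collection` or named list of gene vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
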