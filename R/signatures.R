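#' Build a 96-context mutation catalog
#'
#' Counts qualifying SNVs into the 96 canonical trinucleotide
#' substitution classes. The inclusion rule follows the study's signature
#' analysis: VAF strictly greater than 0.10 and call quality strictly
#' greater than 20; all consequence classes (including synonymous,
#' intronic and intergenic) contribute. Purine-reference variants are
#' reverse-complemented into the pyrimidine convention by
#' [context_class()].
#'
#' @param records Variant data.frame; non-SNV rows are ignored.
#' @param sample_id Optional id stamped on the catalog.
#' @param min_vaf,min_quality Strict inclusion thresholds.
#' @return A `mutation_catalog`: named integer vector over
#'   [sbs_classes()] with attributes `sample_id` and `n_mutations`.
#' @export
build_catalog <- function(records, sample_id = NULL, min_vaf = 0.10,
                          min_quality = 20) {
  assert_columns(records, c("kind", "ref", "alt", "context", "vaf", "call_quality"),
                 "records")
  snv <- records[records$kind == "SNV" & records$vaf > min_vaf &
                   records$call_quality > min_quality, , drop = FALSE]
  if (any(!nzchar(snv$context))) stop("SNV lacking trinucleotide context")
  counts <- stats::setNames(integer(96), sbs_classes())
  if (nrow(snv) > 0) {
    cls <- context_class(snv$ref, snv$alt, snv$context)
    tab <- table(factor(cls, levels = sbs_classes()))
    counts <- stats::setNames(as.integer(tab), sbs_classes())
  }
  structure(counts,
            sample_id = sample_id %||% (if (nrow(records) > 0) records$sample_id[1] else NA_character_),
            n_mutations = sum(counts),
            class = "mutation_catalog")
}

# golden-section minimisation of f on [lo, hi]
golden_section <- function(f, lo, hi, tol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Refit a mutation catalog against a reference signature matrix
#'
#' Models the normalized catalog as a convex combination of reference
#' signature rows and estimates the nonnegative per-signature weights by
#' iterative forward selection: at each step, each candidate signature's
#' weight is optimized in isolation by a golden-section line search on
#' its feasible interval (holding the others fixed, total weight capped
#' at 1), and the single signature giving the largest decrease in squared
#' reconstruction error is updated; iteration stops when the best
#' available improvement falls below `tol` as a fraction of the current
#' squared error. Weights below
#' `min_contribution` are then pruned to zero and the surviving weights
#' re-optimized by the same coordinate scheme (re-pruning if a weight
#' falls below the floor again). Any unassigned mass `1 - sum(weights)`
#' is reported as unexplained. The procedure is deterministic.
#'
#' @param catalog A `mutation_catalog` (or named 96-vector of counts),
#'   total at least 1.
#' @param signatures Reference `signature_matrix`.
#' @param min_contribution Minimum reported weight (default 0.06).
#' @param tol Relative convergence tolerance on the squared-error improvement.
#' @return A `signature_fit`: list with `weights` (named, all at least
#'   `min_contribution`), `unexplained`, `sse`, `n_mutations`, and
#'   `reconstruction` (fitted 96-vector).
#' @export
fit_signatures <- function(catalog, signatures, min_contribution = 0.06,
                           tol = 1e-3) {
  signatures <- as_signature_matrix(signatures)
  counts <- as.numeric(catalog)
  if (length(counts) != 96) stop("catalog must have 96 classes")
  total <- sum(counts)
  if (total < 1) stop("empty catalog: signature refitting needs at least one mutation")
  p <- counts / total
  S <- unclass(signatures)
  n_sig <- nrow(S)
  w <- stats::setNames(numeric(n_sig), rownames(S))

  sse_of <- function(w) {
    r <- p - as.numeric(crossprod(S, w))
    sum(r * r)
  }

  optimise_coord <- function(w, j) {
    cap <- 1 - sum(w[-j])
    if (cap <= 0) return(w[j])
    golden_section(function(v) {
      wj <- w; wj[j] <- v; sse_of(wj)
    }, 0, cap)
  }

  current <- sse_of(w)
  repeat {
    best_j <- 0L; best_v <- 0; best_sse <- current
    for (j in seq_len(n_sig)) {
      v <- optimise_coord(w, j)
      wj <- w; wj[j] <- v
      s <- sse_of(wj)
      if (s < best_sse - 1e-15) {
        best_sse <- s; best_j <- j; best_v <- v
      }
    }
    # tol is relative to the current squared error
    if (best_j == 0L || current - best_sse < tol * current) break
    w[best_j] <- best_v
    current <- best_sse
  }

  # prune and re-optimize until stable
  repeat {
    small <- w > 0 & w < min_contribution
    if (!any(small)) break
    w[small] <- 0
    active <- which(w > 0)
    if (length(active) == 0) break
    repeat {
      improved <- FALSE
      for (j in active) {
        v <- optimise_coord(w, j)
        wj <- w; wj[j] <- v
        s <- sse_of(wj)
        if (s < current * (1 - 1e-6) - 1e-12) {
          w[j] <- v; current <- s; improved <- TRUE
        }
      }
      if (!improved) break
    }
  }

  keep <- w >= min_contribution
  weights <- w[keep]
  structure(
    list(
      weights = weights[order(-weights)],
      unexplained = 1 - sum(weights),
      sse = sse_of(w),
      n_mutations = total,
      reconstruction = as.numeric(crossprod(S, w))
    ),
    class = "signature_fit"
  )
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature refit over", x$n_mutations, "mutations\n")
  for (s in names(x$weights)) {
    cat(sprintf("  %-8s %5.3f\n", s, x$weights[[s]]))
  }
  cat(sprintf("  unexplained %5.3f, SSE %.3g\n", x$unexplained, x$sse))
  invisible(x)
}

#' Cosine similarity between a catalog and each reference signature
#'
#' @param catalog A `mutation_catalog` or 96-vector.
#' @param signatures Reference `signature_matrix`.
#' @return Named numeric vector of cosine similarities.
#' @export
catalog_cosine <- function(catalog, signatures) {
  signatures <- as_signature_matrix(signatures)
  v <- as.numeric(catalog)
  apply(signatures, 1, function(s) {
    sum(v * s) / sqrt(sum(v^2) * sum(s^2))
  })
}

#' Write a catalog (96-row TSV) and a signature fit (JSON)
#'
#' @param catalog A `mutation_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(
    data.frame(class = sbs_classes(), count = as.integer(catalog)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @param fit A `signature_fit`.
#' @rdname write_catalog
#' @export
write_signature_fit <- function(fit, path) {
  jsonlite::write_json(
    list(weights = as.list(fit$weights), unexplained = fit$unexplained,
         sse = fit$sse, n_mutations = fit$n_mutations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
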