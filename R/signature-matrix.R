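#' Synthetic reference signature matrix
#'
#' Builds a deterministic, synthetic stand-in for a COSMIC-style
#' single-base-substitution reference catalog: `n_signatures` rows, each a
#' probability distribution over the 96 canonical trinucleotide classes.
#' Rows are sparse and concentrated on distinct subsets of classes so that
#' different signatures are well separated (pairwise cosine similarity is
#' low), which is the property refitting algorithms rely on. The matrix is
#' synthetic: its rows are not the published COSMIC signatures, and results
#' obtained with it are only meaningful for testing and simulation. Any
#' matrix in the same CSV schema (see [read_signature_matrix()]) can be used
#' in its place for real analyses.
#'
#' @param n_signatures Number of signature rows (default 30, mirroring the
#'   size of the COSMIC v2 catalog).
#' @param concentration Dirichlet-like concentration of each row on its
#'   preferred classes; smaller values give spikier signatures.
#' @param seed Integer seed; the default gives the matrix shipped with the
#'   package examples.
#' @return A `signature_matrix`: numeric matrix with signature ids
#'   (`"Sig1"`, ...) as rownames and the 96 classes as colnames; each row
#'   sums to 1.
#' @export
#' @examples
#' S <- synthetic_signatures()
#' dim(S)
#' rowSums(S)[1:3]
synthetic_signatures <- function(n_signatures = 30, concentration = 0.08, seed = 909) {
  stopifnot(n_signatures >= 1, concentration > 0)
  classes <- sbs_classes()
  S <- with_stream(seed, 0, {
    m <- matrix(0, n_signatures, 96, dimnames = list(paste0("Sig", seq_len(n_signatures)), classes))
    for (i in seq_len(n_signatures)) {
      # gamma draws ~ Dirichlet; a handful of heavy classes per signature
      g <- stats::rgamma(96, shape = concentration)
      peaks <- sample.int(96, 6)
      g[peaks] <- g[peaks] + stats::rgamma(6, shape = 3)
      m[i, ] <- g / sum(g)
    }
    m
  })
  as_signature_matrix(S)
}

as_signature_matrix <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 96)
  if (is.null(rownames(m))) stop("signature matrix must have signature ids as rownames")
  colnames(m) <- colnames(m) %||% sbs_classes()
  if (!identical(colnames(m), sbs_classes())) {
    if (!setequal(colnames(m), sbs_classes())) {
      stop("signature matrix columns must be the 96 canonical classes")
    }
    m <- m[, sbs_classes(), drop = FALSE]
  }
  bad <- abs(rowSums(m) - 1) > 1e-6
  if (any(bad)) {
    stop(
      "signature matrix rows must sum to 1; offending rows: ",
      paste(rownames(m)[bad], collapse = ", ")
    )
  }
  if (any(m < 0)) stop("signature matrix entries must be nonnegative")
  structure(m, class = c("signature_matrix", "matrix", "array"))
}

#' Read / write a reference signature matrix (CSV)
#'
#' The CSV schema is one row per signature: a `signature` id column
#' followed by 96 columns named by substitution class (`"A[C>A]A"`, ...).
#' Rows must sum to 1 within 1e-6.
#'
#' @param path File path.
#' @return For `read_signature_matrix`, a `signature_matrix`.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "signature") stop("first column must be 'signature'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$signature
  as_signature_matrix(m)
}

#' @param x A `signature_matrix`.
#' @rdname read_signature_matrix
#' @export
write_signature_matrix <- function(x, path) {
  x <- as_signature_matrix(x)
  df <- data.frame(signature = rownames(x), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(x), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
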