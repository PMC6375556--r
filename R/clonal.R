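#' Cluster variants into clones by binomial mixture of VAFs
#'
#' Fits one-dimensional binomial mixture models to the (alt reads, depth)
#' pairs of a sample's kept variants by expectation-maximization, for
#' k = 1..`k_max` components, and selects k by the Bayesian information
#' criterion. Initialization uses a fixed quantile grid of the observed
#' VAFs, so the fit is deterministic; `seed` is used only for small
#' jitter restarts when a component empties. Components are reported as
#' clone clusters of at least two members (a singleton assignment is
#' merged into the nearest surviving component). This is a deliberately
#' simplified, VAF-only clonality model: it assumes diploid, copy-neutral
#' sites and does not attempt the copy-number-aware inference of
#' dedicated cancer-exome clonality tools.
#'
#' @param records Variant data.frame with `record_id`,
#'   `tumour_alt_reads`, `tumour_depth` (at least 2 rows).
#' @param k_max Largest number of components tried.
#' @param seed Integer seed for jitter restarts.
#' @param sample_id Optional id stamped on clusters.
#' @return List of clone clusters, each a list with `sample_id`, `label`,
#'   `members` (record ids), `mean_vaf`, `size`; attribute `k` holds the
#'   selected component count.
#' @export
cluster_vafs <- function(records, k_max = 5, seed = 1L, sample_id = NULL) {
  assert_columns(records, c("record_id", "tumour_alt_reads", "tumour_depth"),
                 "records")
  n <- nrow(records)
  if (n < 2) stop("clone clustering needs at least 2 variants")
  x <- records$tumour_alt_reads
  d <- records$tumour_depth
  vaf <- x / d
  sid <- sample_id %||% (records$sample_id[1] %||% NA_character_)

  fit_k <- function(k) {
    mu <- stats::quantile(vaf, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
    pi_k <- rep(1 / k, k)
    ll_old <- -Inf
    for (iter in 1:500) {
      logd <- vapply(seq_len(k), function(j) {
        stats::dbinom(x, d, mu[j], log = TRUE) + log(pi_k[j])
      }, numeric(n))
      if (k == 1) logd <- matrix(logd, ncol = 1)
      m <- apply(logd, 1, max)
      resp <- exp(logd - m)
      rs <- rowSums(resp)
      resp <- resp / rs
      ll <- sum(m + log(rs))
      nk <- colSums(resp)
      if (any(nk < 1e-8)) {
        # degenerate component: jitter its mean and continue
        empty <- which(nk < 1e-8)
        mu[empty] <- with_stream(seed, 41L + iter, stats::runif(length(empty), 0.02, 0.6))
        next
      }
      pi_k <- nk / n
      mu <- colSums(resp * x) / colSums(resp * d)
      mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
      if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8) break
      ll_old <- ll
    }
    assign <- apply(logd, 1, which.max)
    list(k = k, mu = mu, pi = pi_k, ll = ll, assign = assign,
         bic = -2 * ll + (2 * k - 1) * log(n))
  }

  fits <- lapply(seq_len(min(k_max, n)), fit_k)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]

  assign <- best$assign
  # enforce minimum cluster size 2 by merging singletons into the
  # component with the closest mean
  repeat {
    sizes <- table(factor(assign, levels = seq_len(best$k)))
    lone <- as.integer(names(sizes)[sizes == 1])
    if (length(lone) == 0 || length(unique(assign)) == 1) break
    j <- lone[1]
    i <- which(assign == j)
    others <- setdiff(unique(assign), j)
    tgt <- others[which.min(abs(best$mu[others] - vaf[i]))]
    assign[i] <- tgt
  }

  labels <- sort(unique(assign))
  clusters <- lapply(seq_along(labels), function(ci) {
    i <- which(assign == labels[ci])
    list(
      sample_id = sid, label = paste0("clone", ci),
      members = records$record_id[i],
      mean_vaf = sum(x[i]) / sum(d[i]),
      size = length(i)
    )
  })
  clusters <- clusters[order(-vapply(clusters, `[[`, 0, "mean_vaf"))]
  for (ci in seq_along(clusters)) clusters[[ci]]$label <- paste0("clone", ci)
  attr(clusters, "k") <- length(clusters)
  attr(clusters, "bic") <- best$bic
  clusters
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Track clones between diagnostic and residual timepoints
#'
#' Matches diagnostic and residual clone clusters greedily by descending
#' Jaccard overlap of their member variant ids; each cluster is used at
#' most once. A matched pair with Jaccard >= `match_threshold` is a
#' persistent clone; an unmatched residual cluster is emergent; an
#' unmatched diagnostic cluster is extinct.
#'
#' @param diagnostic,residual Cluster lists from [cluster_vafs()].
#' @param match_threshold Minimum Jaccard overlap for persistence.
#' @param patient_id Optional id stamped on trajectories.
#' @return Data.frame: `patient_id`, `clone`, `fate`
#'   (persistent/emergent/extinct), `diagnostic_cluster`,
#'   `residual_cluster`, `vaf_diagnostic`, `vaf_residual`,
#'   `n_defining_variants`; the defining variant ids are in the
#'   list-column `defining_variants`.
#' @export
track_clones <- function(diagnostic, residual, match_threshold = 0.5,
                         patient_id = NA_character_) {
  check_disjoint <- function(clusters, label) {
    ids <- unlist(lapply(clusters, `[[`, "members"))
    if (anyDuplicated(ids)) {
      stop("clusters within the ", label, " sample share a variant")
    }
  }
  check_disjoint(diagnostic, "diagnostic")
  check_disjoint(residual, "residual")

  nd <- length(diagnostic); nr <- length(residual)
  pairs <- expand.grid(d = seq_len(nd), r = seq_len(nr))
  if (nrow(pairs) > 0) {
    pairs$j <- mapply(function(di, ri) {
      jaccard(diagnostic[[di]]$members, residual[[ri]]$members)
    }, pairs$d, pairs$r)
    pairs <- pairs[order(-pairs$j, pairs$d, pairs$r), , drop = FALSE]
  }
  used_d <- logical(nd); used_r <- logical(nr)
  match_d <- rep(NA_integer_, nd)
  for (i in seq_len(nrow(pairs))) {
    di <- pairs$d[i]; ri <- pairs$r[i]
    if (pairs$j[i] < match_threshold) break
    if (used_d[di] || used_r[ri]) next
    used_d[di] <- used_r[ri] <- TRUE
    match_d[di] <- ri
  }

  rows <- list()
  add <- function(fate, dref, rref) {
    members <- unique(c(
      if (!is.na(dref)) diagnostic[[dref]]$members,
      if (!is.na(rref)) residual[[rref]]$members
    ))
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = patient_id,
      clone = paste0("T", length(rows) + 1),
      fate = fate,
      diagnostic_cluster = if (is.na(dref)) NA_character_ else diagnostic[[dref]]$label,
      residual_cluster = if (is.na(rref)) NA_character_ else residual[[rref]]$label,
      vaf_diagnostic = if (is.na(dref)) NA_real_ else diagnostic[[dref]]$mean_vaf,
      vaf_residual = if (is.na(rref)) NA_real_ else residual[[rref]]$mean_vaf,
      n_defining_variants = length(members),
      stringsAsFactors = FALSE
    )
    rows[[length(rows)]]$defining_variants <<- I(list(members))
  }
  for (di in seq_len(nd)) {
    if (!is.na(match_d[di])) add("persistent", di, match_d[di]) else add("extinct", di, NA)
  }
  for (ri in seq_len(nr)) {
    if (!used_r[ri]) add("emergent", NA, ri)
  }
  if (length(rows) == 0) {
    return(data.frame(
      patient_id = character(0), clone = character(0), fate = character(0),
      diagnostic_cluster = character(0), residual_cluster = character(0),
      vaf_diagnostic = numeric(0), vaf_residual = numeric(0),
      n_defining_variants = integer(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' River-plot-ready table of clone trajectories
#'
#' One row per (clone, timepoint) with the clone's mean VAF as its
#' fraction at that timepoint; extinct clones contribute only a
#' diagnostic row and emergent clones only a residual row.
#'
#' @param trajectories Output of [track_clones()].
#' @return Data.frame: `patient_id`, `clone`, `fate`, `timepoint`,
#'   `fraction`.
#' @export
river_table <- function(trajectories) {
  rows <- list()
  for (i in seq_len(nrow(trajectories))) {
    tr <- trajectories[i, ]
    if (!is.na(tr$vaf_diagnostic)) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = tr$patient_id, clone = tr$clone, fate = tr$fate,
        timepoint = "diagnostic", fraction = tr$vaf_diagnostic,
        stringsAsFactors = FALSE
      )
    }
    if (!is.na(tr$vaf_residual)) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = tr$patient_id, clone = tr$clone, fate = tr$fate,
        timepoint = "residual", fraction = tr$vaf_residual,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(0), clone = character(0),
                      fate = character(0), timepoint = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a two-timepoint multi-clone patient
#'
#' Plants known clones at well-separated VAFs in a diagnostic and a
#' residual sample. Persistent clones keep their variant ids (and VAF
#' slot) across timepoints, extinct clones appear only at diagnosis, and
#' emergent clones only in residual disease, occupying freed VAF slots.
#' Read depths are Poisson around `depth`; alt counts are binomial at the
#' clone VAF (clamped to at least 1 read).
#'
#' @param n_clones Number of diagnostic clones (2-4).
#' @param n_extinct How many diagnostic clones disappear (>= 1,
#'   < `n_clones`).
#' @param n_emergent How many new clones appear in residual disease
#'   (at most `n_extinct` so VAF slots stay separated).
#' @param depth Mean sequencing depth.
#' @param variants_per_clone Variants defining each clone.
#' @param seed Integer seed.
#' @param patient_id Id stamped on records.
#' @return List: `diagnostic`, `residual` (minimal variant data.frames),
#'   `truth` (data.frame: `clone`, `fate`, `vaf`, `n_variants`),
#'   `membership` (record_id to true clone map).
#' @export
simulate_clone_patient <- function(n_clones = 3, n_extinct = 1, n_emergent = 1,
                                   depth = 200, variants_per_clone = 30,
                                   seed = 1L, patient_id = "P1") {
  stopifnot(n_clones >= 2, n_clones <= 4, n_extinct >= 1, n_extinct < n_clones,
            n_emergent >= 0, n_emergent <= n_extinct)
  grid <- c(0.50, 0.35, 0.22, 0.12)
  vafs <- grid[seq_len(n_clones)]
  n_persistent <- n_clones - n_extinct
  fates <- c(rep("persistent", n_persistent), rep("extinct", n_extinct))
  emergent_vafs <- grid[n_persistent + seq_len(n_emergent)]

  with_stream(seed, 51L, {
    draw <- function(vaf, clone, tp, m) {
      d <- pmax(30, stats::rpois(m, depth))
      a <- pmax(1, stats::rbinom(m, d, vaf))
      data.frame(
        record_id = sprintf("%s_%s_V%03d", patient_id, clone, seq_len(m)),
        sample_id = paste0(patient_id, "_", tp),
        tumour_alt_reads = a, tumour_depth = d, vaf = a / d,
        stringsAsFactors = FALSE
      )
    }
    diag_rows <- list(); resid_rows <- list(); truth <- list(); membership <- list()
    for (ci in seq_len(n_clones)) {
      clone <- paste0("C", ci)
      dd <- draw(vafs[ci], clone, "diagnostic", variants_per_clone)
      diag_rows[[ci]] <- dd
      membership[[length(membership) + 1]] <- data.frame(
        record_id = dd$record_id, clone = clone, stringsAsFactors = FALSE
      )
      if (fates[ci] == "persistent") {
        rr <- draw(vafs[ci], clone, "residual", variants_per_clone)
        rr$record_id <- dd$record_id # same variants define the clone
        rr$sample_id <- paste0(patient_id, "_residual")
        resid_rows[[length(resid_rows) + 1]] <- rr
      }
      truth[[ci]] <- data.frame(clone = clone, fate = fates[ci], vaf = vafs[ci],
                                n_variants = variants_per_clone,
                                stringsAsFactors = FALSE)
    }
    for (ei in seq_len(n_emergent)) {
      clone <- paste0("E", ei)
      rr <- draw(emergent_vafs[ei], clone, "residual", variants_per_clone)
      resid_rows[[length(resid_rows) + 1]] <- rr
      membership[[length(membership) + 1]] <- data.frame(
        record_id = rr$record_id, clone = clone, stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1]] <- data.frame(
        clone = clone, fate = "emergent", vaf = emergent_vafs[ei],
        n_variants = variants_per_clone, stringsAsFactors = FALSE
      )
    }
    list(
      diagnostic = do.call(rbind, diag_rows),
      residual = do.call(rbind, resid_rows),
      truth = do.call(rbind, truth),
      membership = do.call(rbind, membership)
    )
  })
}
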