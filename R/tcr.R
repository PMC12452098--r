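#' Build a paired-chain clonotype table from AIRR-style records
#'
#' Retains cells carrying exactly one productive TRA and one TRB chain;
#' cells with two or more chains of the same locus are dropped and tallied.
#' The clonotype key is the concatenation of CDR3 alpha amino-acid sequence,
#' TRA V/J calls, CDR3 beta sequence and TRB V/J calls; counts are cells per
#' key per sample.
#'
#' @param tcr data.frame with columns `cell_id`, `locus`, `v_call`,
#'   `j_call`, `junction_aa` (one row per chain).
#' @param cell_meta per-cell metadata with `cell_id` and `sample_id`.
#' @return object of class `icisig_clonotypes`: data.frame with
#'   `clonotype_key`, `cdr3a`, `va`, `ja`, `cdr3b`, `vb`, `jb`, `sample_id`,
#'   `count`; attributes `sample_totals` (paired-TCR count per sample) and
#'   `dropped` (tally of excluded cells by reason).
#' @export
build_clonotypes <- function(tcr, cell_meta) {
  need <- c("cell_id", "locus", "v_call", "j_call", "junction_aa")
  if (!all(need %in% names(tcr))) {
    stop_cfg("tcr records need columns ", paste(need, collapse = ", "))
  }
  ok_aa <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", tcr$junction_aa)
  n_malformed <- sum(!ok_aa)
  tcr <- tcr[ok_aa, , drop = FALSE]

  counts <- table(tcr$cell_id, factor(tcr$locus, levels = c("TRA", "TRB")))
  cells <- rownames(counts)
  n_a <- counts[, "TRA"]
  n_b <- counts[, "TRB"]
  multi <- cells[n_a > 1 | n_b > 1]
  unpaired <- cells[(n_a == 0 | n_b == 0) & !(cells %in% multi)]
  keep <- setdiff(cells, c(multi, unpaired))

  a <- tcr[tcr$locus == "TRA" & tcr$cell_id %in% keep, ]
  b <- tcr[tcr$locus == "TRB" & tcr$cell_id %in% keep, ]
  a <- a[match(keep, a$cell_id), ]
  b <- b[match(keep, b$cell_id), ]
  sample_id <- cell_meta$sample_id[match(keep, cell_meta$cell_id)]
  if (any(is.na(sample_id))) {
    stop_cfg("TCR records reference cell ids absent from cell_meta")
  }
  key <- paste(a$junction_aa, a$v_call, a$j_call,
               b$junction_aa, b$v_call, b$j_call, sep = "|")
  df <- data.frame(clonotype_key = key, cdr3a = a$junction_aa, va = a$v_call,
                   ja = a$j_call, cdr3b = b$junction_aa, vb = b$v_call,
                   jb = b$j_call, sample_id = sample_id,
                   stringsAsFactors = FALSE)
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   by = df[c("clonotype_key", "cdr3a", "va", "ja", "cdr3b",
                             "vb", "jb", "sample_id")], FUN = sum)
  totals <- tapply(agg$count, agg$sample_id, sum)
  structure(agg,
            class = c("icisig_clonotypes", "data.frame"),
            sample_totals = setNames(as.integer(totals), names(totals)),
            dropped = c(multi_chain = length(multi),
                        unpaired = length(unpaired),
                        malformed_junction = n_malformed))
}

#' Normalized clonotype size
#'
#' The fraction of a sample's paired-TCR repertoire occupied by one
#' clonotype: the clonotype's paired-TCR count divided by the sample's
#' total paired-TCR count.
#'
#' @param count clonotype paired-TCR count(s), positive.
#' @param sample_total the sample's total paired-TCR count.
#' @return `count / sample_total`.
#' @export
normalized_size <- function(count, sample_total) {
  if (any(sample_total <= 0)) stop_cfg("sample total must be positive")
  if (any(count <= 0) || any(count > sample_total)) {
    stop_cfg("counts must satisfy 0 < count <= sample_total")
  }
  count / sample_total
}

#' Discretize clonotype abundances
#'
#' Bins normalized clonotype sizes into the five half-open intervals
#' `(0, 1e-5]`, `(1e-5, 1e-4]`, `(1e-4, 1e-3]`, `(1e-3, 0.01]`,
#' `(0.01, 1]`. Normalized sizes are strictly positive, so the half-open
#' `(lo, hi]` convention loses nothing.
#'
#' @param fractions normalized sizes in `(0, 1]`.
#' @return factor of bin labels.
#' @export
discretize_abundance <- function(fractions) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop_cfg("fractions must lie in (0, 1]")
  }
  cut(fractions, breaks = c(0, 1e-5, 1e-4, 1e-3, 0.01, 1), right = TRUE)
}

#' Gini-Simpson clonotype diversity
#'
#' `1 - sum(p_i^2)` with `p_i` the clonotype frequencies: the probability
#' that two sampled paired TCRs belong to different clonotypes. Higher
#' values mean a more diverse repertoire; a single clone scores 0 and `K`
#' equal clones score `1 - 1/K`.
#'
#' @param counts positive clonotype counts of one sample.
#' @return diversity in `[0, 1)`.
#' @export
simpson_diversity <- function(counts) {
  if (!length(counts) || sum(counts) <= 0) {
    stop_cfg("need at least one clonotype with positive count")
  }
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Per-sample repertoire diversity
#'
#' @param ct an [build_clonotypes()] table.
#' @return data.frame: `sample_id`, `n_clonotypes`, `total`, `simpson`.
#' @export
sample_diversity <- function(ct) {
  stopifnot(inherits(ct, "icisig_clonotypes"))
  by_sample <- split(ct$count, ct$sample_id)
  data.frame(
    sample_id = names(by_sample),
    n_clonotypes = vapply(by_sample, length, integer(1)),
    total = vapply(by_sample, sum, numeric(1)),
    simpson = vapply(by_sample, simpson_diversity, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Clonotype dynamics between two visits
#'
#' Partitions the clonotypes of two samples into shared and
#' sample-exclusive sets; a shared clonotype is expanded when its normalized
#' size at v2 exceeds its normalized size at v1, contracted when smaller,
#' and counted as equal otherwise.
#'
#' @param ct an [build_clonotypes()] table containing both samples.
#' @param sample_v1,sample_v2 sample ids (distinct).
#' @return list with `shared` (data.frame: key, sizes and status),
#'   `unique_v1`, `unique_v2` (data.frames), and counts `n_expanded`,
#'   `n_contracted`, `n_equal`.
#' @export
clonotype_dynamics <- function(ct, sample_v1, sample_v2) {
  stopifnot(inherits(ct, "icisig_clonotypes"))
  if (identical(sample_v1, sample_v2)) {
    stop_cfg("the two samples must be distinct")
  }
  tot <- attr(ct, "sample_totals")
  if (!all(c(sample_v1, sample_v2) %in% names(tot))) {
    stop_cfg("both samples must be present in the clonotype table")
  }
  t1 <- ct[ct$sample_id == sample_v1, ]
  t2 <- ct[ct$sample_id == sample_v2, ]
  f1 <- setNames(normalized_size(t1$count, tot[[sample_v1]]),
                 t1$clonotype_key)
  f2 <- setNames(normalized_size(t2$count, tot[[sample_v2]]),
                 t2$clonotype_key)
  shared_keys <- intersect(names(f1), names(f2))
  shared <- data.frame(
    clonotype_key = shared_keys,
    size_v1 = unname(f1[shared_keys]), size_v2 = unname(f2[shared_keys]),
    stringsAsFactors = FALSE
  )
  shared$status <- with(shared, ifelse(size_v2 > size_v1, "expanded",
                                       ifelse(size_v2 < size_v1,
                                              "contracted", "equal")))
  list(
    shared = shared,
    unique_v1 = t1[!t1$clonotype_key %in% shared_keys, , drop = FALSE],
    unique_v2 = t2[!t2$clonotype_key %in% shared_keys, , drop = FALSE],
    n_expanded = sum(shared$status == "expanded"),
    n_contracted = sum(shared$status == "contracted"),
    n_equal = sum(shared$status == "equal")
  )
}

#' Configuration of the simplified TCR distance
#'
#' A transparent sequence distance over paired clonotypes: per chain, the
#' Levenshtein distance between CDR3 amino-acid strings times the
#' substitution weight, weighted per chain (beta weighted 3x alpha,
#' following the convention that the beta chain contributes most of the
#' antigen contact), plus a flat penalty per mismatching V gene. It keeps
#' the geometry of CDR3-centric repertoire distances at desk scale without
#' the full CDR1/2/2.5 and gap-penalized alignment machinery.
#'
#' @param subst_cost per-substitution cost. @param gap_cost
#'   insertion/deletion cost. @param v_penalty added once per chain whose V
#'   gene differs. @param chain_weights named weights for `alpha` and
#'   `beta`.
#' @return list of class `icisig_tcrdist_config`.
#' @export
tcr_distance_config <- function(subst_cost = 1, gap_cost = 1, v_penalty = 4,
                                chain_weights = c(alpha = 1, beta = 3)) {
  if (subst_cost < 0 || gap_cost < 0 || v_penalty < 0 ||
      any(chain_weights < 0)) {
    stop_cfg("costs must be nonnegative")
  }
  structure(list(subst_cost = subst_cost, gap_cost = gap_cost,
                 v_penalty = v_penalty, chain_weights = chain_weights),
            class = "icisig_tcrdist_config")
}

#' Distance between two paired clonotypes
#'
#' @param a,b lists or one-row data.frames with fields `cdr3a`, `va`,
#'   `cdr3b`, `vb`.
#' @param config an [tcr_distance_config()].
#' @return nonnegative distance; 0 iff CDR3s and V genes all match.
#' @export
tcr_distance <- function(a, b, config = tcr_distance_config()) {
  if (!nzchar(a$cdr3a) || !nzchar(a$cdr3b) || !nzchar(b$cdr3a) ||
      !nzchar(b$cdr3b)) {
    stop_cfg("empty CDR3 sequence")
  }
  w <- config$chain_weights
  lev <- function(x, y) {
    as.numeric(adist(x, y, costs = list(ins = config$gap_cost,
                                        del = config$gap_cost,
                                        sub = config$subst_cost)))
  }
  w[["alpha"]] * (lev(a$cdr3a, b$cdr3a) +
                    config$v_penalty * (a$va != b$va)) +
    w[["beta"]] * (lev(a$cdr3b, b$cdr3b) +
                     config$v_penalty * (a$vb != b$vb))
}

# All-pairs distance matrix between two sets of clonotype records.
tcr_distance_matrix <- function(x, y, config = tcr_distance_config()) {
  costs <- list(ins = config$gap_cost, del = config$gap_cost,
                sub = config$subst_cost)
  w <- config$chain_weights
  da <- adist(x$cdr3a, y$cdr3a, costs = costs)
  db <- adist(x$cdr3b, y$cdr3b, costs = costs)
  va <- outer(x$va, y$va, `!=`) * config$v_penalty
  vb <- outer(x$vb, y$vb, `!=`) * config$v_penalty
  w[["alpha"]] * (da + va) + w[["beta"]] * (db + vb)
}

#' Mean repertoire distance within and between response groups
#'
#' For every eligible pair of samples, the mean distance over all
#' cross-sample clonotype pairs (unique clonotypes, unweighted by clone
#' size, unless `weight_by_frequency`); pairs of samples from the same
#' donor (different visits) are excluded. Pair means are then averaged
#' within three categories: within group 1, between groups, within group 2.
#'
#' @param ct an [build_clonotypes()] table.
#' @param sample_groups named vector sample_id -> group (two groups).
#' @param sample_donors named vector sample_id -> donor id, used to exclude
#'   same-donor cross-visit pairs.
#' @param config an [tcr_distance_config()].
#' @param weight_by_frequency weight clonotype pairs by the product of
#'   their normalized sizes instead of uniformly.
#' @return list with `category_means` (named numeric; `NA` where no
#'   eligible pair exists) and `pairs` (per-pair data.frame).
#' @export
group_similarity <- function(ct, sample_groups, sample_donors,
                             config = tcr_distance_config(),
                             weight_by_frequency = FALSE) {
  stopifnot(inherits(ct, "icisig_clonotypes"))
  samples <- sort(unique(ct$sample_id))
  g <- as.character(sample_groups[samples])
  if (any(is.na(g))) stop_cfg("every sample needs a group")
  lev <- unique(g)
  if (length(lev) != 2) stop_cfg("exactly two groups are required")
  donors <- sample_donors[samples]
  tot <- attr(ct, "sample_totals")
  recs <- split(ct, ct$sample_id)

  pairs <- utils::combn(seq_along(samples), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (donors[i1] == donors[i2]) return(NULL) # same donor, other visit
    r1 <- recs[[samples[i1]]]; r2 <- recs[[samples[i2]]]
    d <- tcr_distance_matrix(r1, r2, config)
    if (weight_by_frequency) {
      w <- outer(r1$count / tot[[samples[i1]]],
                 r2$count / tot[[samples[i2]]])
      md <- sum(d * w) / sum(w)
    } else {
      md <- mean(d)
    }
    cat1 <- g[i1]; cat2 <- g[i2]
    category <- if (cat1 == cat2) paste0("within-", cat1) else "between"
    data.frame(sample_1 = samples[i1], sample_2 = samples[i2],
               category = category, mean_distance = md,
               stringsAsFactors = FALSE)
  })
  pair_df <- do.call(rbind, rows)
  cats <- c(paste0("within-", lev[1]), "between", paste0("within-", lev[2]))
  means <- vapply(cats, function(cc) {
    v <- pair_df$mean_distance[pair_df$category == cc]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  list(category_means = means, pairs = pair_df)
}
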