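#' Simulate a multi-donor CITE-seq + paired-TCR cohort
#'
#' Generates UMI counts, surface-marker (ADT) counts, per-cell metadata and
#' paired TCR chains for a two-group cohort with known planted effects.
#'
#' RNA counts are negative binomial around a lognormal per-gene baseline.
#' The baseline allocates configurable fractions of each cell's library to
#' mitochondrial ("MT-") and ribosomal ("RPS"/"RPL") genes so QC percentages
#' behave like real data. Subset and state identity raise the planted marker
#' genes of a cell's subset/state multiplicatively; planted differential
#' effects multiply the feature mean by `2^log2fc` for cells of the stated
#' (subset, group). ADT counts are a Poisson cell signal plus Poisson ambient
#' background; isotype controls carry ambient background only. Ambient-only
#' "empty droplet" barcodes are emitted for the ADT background model.
#'
#' Clone sizes are geometric per subset, with expected size increasing with
#' subset maturity. A clonotype is drawn from the group-shared motif pool
#' with probability `tcr_group_sharing` (yielding identical or near-identical
#' TCRs across samples of the same group) and generated privately otherwise.
#'
#' @param config an [sim_config()] object.
#' @return An object of class `icisig_dataset`: a list with
#'   `gene_counts` (cells x genes, sparse), `adt_counts` (cells x markers,
#'   isotype controls last), `adt_background` (ambient-only droplets x
#'   markers), `cell_meta` (cell_id, donor_id, sample_id, visit,
#'   response_group, true_subset, true_state), `tcr` (AIRR-style long
#'   data.frame: cell_id, locus, v_call, j_call, junction_aa),
#'   `isotype_names`, and a `truth` list (planted effects, marker
#'   assignments, per-cell clonotype ids, shared pools).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "icisig_sim_config"))
  with_seed(config$seed, {
    panel <- sim_panel(config)
    pools <- sim_tcr_pools(config)

    samples <- expand.grid(
      visit = seq_len(config$visits_per_donor),
      donor_idx = seq_len(max(config$n_donors_per_group)),
      group = config$groups,
      stringsAsFactors = FALSE
    )
    samples <- samples[samples$donor_idx <=
                         config$n_donors_per_group[samples$group], ]
    samples$donor_id <- sprintf("%s%02d", samples$group, samples$donor_idx)
    samples$sample_id <- sprintf("%s_v%d", samples$donor_id, samples$visit)
    samples <- samples[order(samples$sample_id), ]

    parts <- lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      gen_sample(config, panel, pools, s$sample_id, s$donor_id, s$group,
                 s$visit)
    })
    assemble_dataset(config, panel, pools, parts)
  })
}

# ---- internal generators ---------------------------------------------------

# Gene/ADT panel: baseline means and planted subset/state marker assignments.
sim_panel <- function(config) {
  fn <- config$feature_names
  n_mito <- length(fn$mito); n_ribo <- length(fn$ribo)
  n_other <- length(fn$other)

  block_means <- function(n, total) {
    raw <- rlnorm(n, 0, 1.2)
    raw / sum(raw) * total
  }
  base <- c(
    block_means(n_mito, config$mito_frac * config$depth_mean),
    block_means(n_ribo, config$ribo_frac * config$depth_mean),
    block_means(n_other,
                (1 - config$mito_frac - config$ribo_frac) * config$depth_mean)
  )
  names(base) <- fn$genes

  planted_feats <- if (is.null(config$planted_de)) character() else
    unique(config$planted_de$feature)
  # subset/state markers come from the generic gene block, never from genes
  # carrying planted differential effects
  candidates <- setdiff(fn$other, planted_feats)
  need <- length(config$subset_names) * config$n_subset_marker_genes +
    length(config$state_names) * config$n_state_marker_genes
  if (length(candidates) < need) {
    stop_cfg("not enough free genes to plant subset/state markers")
  }
  picked <- sample(candidates, need)
  sub_genes <- split(
    picked[seq_len(length(config$subset_names) * config$n_subset_marker_genes)],
    rep(config$subset_names, each = config$n_subset_marker_genes)
  )[config$subset_names]
  state_genes <- split(
    picked[-seq_len(length(config$subset_names) * config$n_subset_marker_genes)],
    rep(config$state_names, each = config$n_state_marker_genes)
  )[config$state_names]
  # marker genes get a solid baseline so they are detectable after elevation
  floor_mean <- quantile(base[fn$other], 0.7)
  for (g in picked) base[g] <- max(base[g], floor_mean)

  adt_names <- c(fn$adt, fn$isotypes)
  need_adt <- length(config$subset_names) * config$n_subset_marker_adts
  if (length(fn$adt) < need_adt) stop_cfg("not enough ADT markers for subsets")
  sub_adts <- split(sample(fn$adt, need_adt),
                    rep(config$subset_names, each = config$n_subset_marker_adts)
  )[config$subset_names]

  ambient <- rep_len(config$ambient_adt_mean, length(adt_names))
  names(ambient) <- adt_names

  list(base_mean = base, subset_genes = sub_genes, state_genes = state_genes,
       subset_adts = sub_adts, adt_names = adt_names, ambient = ambient)
}

# Group-shared clonotype pools: each entry is a complete clonotype.
sim_tcr_pools <- function(config) {
  vj <- vj_catalog()
  lapply(setNames(config$groups, config$groups), function(g) {
    data.frame(
      cdr3a = random_cdr3(config$tcr_pool_size),
      va = sample(vj$va, config$tcr_pool_size, replace = TRUE),
      ja = sample(vj$ja, config$tcr_pool_size, replace = TRUE),
      cdr3b = random_cdr3(config$tcr_pool_size),
      vb = sample(vj$vb, config$tcr_pool_size, replace = TRUE),
      jb = sample(vj$jb, config$tcr_pool_size, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

vj_catalog <- function() {
  list(va = sprintf("TRAV%d", 1:8), ja = sprintf("TRAJ%d", 1:6),
       vb = sprintf("TRBV%d", 1:10), jb = sprintf("TRBJ%d", 1:7))
}

# CDR3 junctions: C...F with a random 6-18 aa interior
random_cdr3 <- function(n) {
  vapply(seq_len(n), function(i) {
    len <- sample(6:18, 1)
    paste0("C", paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = ""),
           "F")
  }, character(1))
}

mutate_cdr3 <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) <= 2) return(s)
  pos <- sample(2:(length(ch) - 1), 1)
  ch[pos] <- sample(AA_ALPHABET, 1)
  paste(ch, collapse = "")
}

# One sample's cells: subset/state assignment, RNA/ADT counts, TCR chains.
gen_sample <- function(config, panel, pools, sample_id, donor_id, group,
                       visit, clone_plan = NULL, n_cells = NULL) {
  n <- if (is.null(n_cells)) config$cells_per_sample else n_cells
  props <- config$subset_props_by_group[group, ]
  if (is.null(clone_plan)) {
    counts <- as.vector(rmultinom(1, n, props))
    subset <- rep(config$subset_names, counts)
  } else {
    subset <- clone_plan$subset_per_cell
    n <- length(subset)
  }
  state <- sample(config$state_names, n, replace = TRUE,
                  prob = config$state_props)
  depth <- rlnorm(1, 0, config$depth_sdlog)

  cell_id <- sprintf("%s_c%04d", sample_id, seq_len(n))
  gene <- gen_gene_counts(config, panel, group, subset, state, depth)
  adt <- gen_adt_counts(config, panel, group, subset)
  rownames(gene) <- rownames(adt) <- cell_id

  if (is.null(clone_plan)) {
    tcrres <- gen_sample_tcr(config, pools[[group]], subset, cell_id)
  } else {
    tcrres <- emit_tcr_records(config, clone_plan$clonotypes[
      clone_plan$clone_per_cell, , drop = FALSE], cell_id,
      clone_plan$clone_ids[clone_plan$clone_per_cell])
  }

  meta <- data.frame(
    cell_id = cell_id, donor_id = donor_id, sample_id = sample_id,
    visit = visit, response_group = group, true_subset = subset,
    true_state = state, stringsAsFactors = FALSE
  )
  list(gene = gene, adt = adt, meta = meta, tcr = tcrres$tcr,
       clonotype = tcrres$clonotype)
}

gen_gene_counts <- function(config, panel, group, subset, state, depth) {
  n <- length(subset)
  genes <- names(panel$base_mean)
  mu <- matrix(panel$base_mean * depth, nrow = n, ncol = length(genes),
               byrow = TRUE, dimnames = list(NULL, genes))
  for (s in unique(subset)) {
    idx <- which(subset == s)
    mu[idx, panel$subset_genes[[s]]] <-
      mu[idx, panel$subset_genes[[s]]] * 2^config$marker_log2fc
  }
  for (st in unique(state)) {
    idx <- which(state == st)
    mu[idx, panel$state_genes[[st]]] <-
      mu[idx, panel$state_genes[[st]]] * 2^config$state_marker_log2fc
  }
  pd <- config$planted_de
  if (!is.null(pd)) {
    pd <- pd[pd$group == group & pd$feature %in% genes, , drop = FALSE]
    if (nrow(pd)) {
      for (i in seq_len(nrow(pd))) {
        idx <- which(subset == pd$subset[i])
        mu[idx, pd$feature[i]] <- mu[idx, pd$feature[i]] * 2^pd$log2fc[i]
      }
    }
  }
  cnt <- matrix(rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu),
                nrow = n, dimnames = list(NULL, genes))
  cnt
}

gen_adt_counts <- function(config, panel, group, subset) {
  n <- length(subset)
  markers <- panel$adt_names
  iso <- config$feature_names$isotypes
  signal <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  real <- setdiff(markers, iso)
  signal[, real] <- config$adt_signal_mean
  for (s in unique(subset)) {
    idx <- which(subset == s)
    signal[idx, panel$subset_adts[[s]]] <-
      signal[idx, panel$subset_adts[[s]]] * 2^config$marker_log2fc
  }
  pd <- config$planted_de
  if (!is.null(pd)) {
    pd <- pd[pd$group == group & pd$feature %in% real, , drop = FALSE]
    if (nrow(pd)) {
      for (i in seq_len(nrow(pd))) {
        idx <- which(subset == pd$subset[i])
        signal[idx, pd$feature[i]] <- signal[idx, pd$feature[i]] * 2^pd$log2fc[i]
      }
    }
  }
  ambient <- matrix(rpois(n * length(markers),
                          rep(panel$ambient, each = n)), n)
  # protein counts are overdispersed (staining/binding efficiency varies
  # between cells), so the cell signal is negative binomial, not Poisson
  cnt <- matrix(rnbinom(length(signal), size = 1 / config$adt_dispersion,
                        mu = signal), n) + ambient
  dimnames(cnt) <- list(NULL, markers)
  cnt
}

# Partition a sample's cells into clones (geometric sizes per subset) and
# emit paired TCR chains; a clone is pool-derived with probability
# `tcr_group_sharing`.
gen_sample_tcr <- function(config, pool, subset, cell_id) {
  n <- length(subset)
  clone_per_cell <- integer(n)
  clonotypes <- list()
  clone_ids <- character()
  k <- 0L
  for (s in unique(subset)) {
    idx <- which(subset == s)
    p <- config$clone_size_shape[[s]]
    left <- length(idx)
    while (left > 0) {
      size <- min(rgeom(1, p) + 1L, left)
      k <- k + 1L
      ct <- draw_clonotype(config, pool)
      clonotypes[[k]] <- ct$clonotype
      clone_ids[k] <- ct$id
      take <- idx[seq_len(size)]
      clone_per_cell[take] <- k
      idx <- idx[-seq_len(size)]
      left <- left - size
    }
  }
  ctab <- do.call(rbind, clonotypes)
  emit_tcr_records(config, ctab[clone_per_cell, , drop = FALSE], cell_id,
                   clone_ids[clone_per_cell])
}

draw_clonotype <- function(config, pool) {
  if (runif(1) < config$tcr_group_sharing) {
    i <- sample(nrow(pool), 1)
    ct <- pool[i, , drop = FALSE]
    id <- sprintf("pool%03d", i)
    if (runif(1) < 0.5) { # near-match: one substitution in one chain
      if (runif(1) < 0.5) ct$cdr3a <- mutate_cdr3(ct$cdr3a)
      else ct$cdr3b <- mutate_cdr3(ct$cdr3b)
      id <- paste0(id, "m", paste(sample(letters, 4, TRUE), collapse = ""))
    }
  } else {
    vj <- vj_catalog()
    ct <- data.frame(
      cdr3a = random_cdr3(1), va = sample(vj$va, 1), ja = sample(vj$ja, 1),
      cdr3b = random_cdr3(1), vb = sample(vj$vb, 1), jb = sample(vj$jb, 1),
      stringsAsFactors = FALSE
    )
    id <- paste0("priv", paste(sample(c(letters, 0:9), 8, TRUE), collapse = ""))
  }
  list(clonotype = ct, id = id)
}

# Long AIRR-style records; a small fraction of cells is unpaired or carries
# a second beta chain.
emit_tcr_records <- function(config, ct_per_cell, cell_id, clonotype_id) {
  n <- length(cell_id)
  a <- data.frame(cell_id = cell_id, locus = "TRA",
                  v_call = ct_per_cell$va, j_call = ct_per_cell$ja,
                  junction_aa = ct_per_cell$cdr3a, stringsAsFactors = FALSE)
  b <- data.frame(cell_id = cell_id, locus = "TRB",
                  v_call = ct_per_cell$vb, j_call = ct_per_cell$jb,
                  junction_aa = ct_per_cell$cdr3b, stringsAsFactors = FALSE)
  u <- runif(n)
  drop_a <- u < config$frac_unpaired / 2
  drop_b <- u >= config$frac_unpaired / 2 & u < config$frac_unpaired
  multi <- u > 1 - config$frac_multi_beta
  extra <- b[multi, , drop = FALSE]
  if (nrow(extra)) extra$junction_aa <- vapply(extra$junction_aa, mutate_cdr3,
                                               character(1))
  tcr <- rbind(a[!drop_a, ], b[!drop_b, ], extra)
  tcr <- tcr[order(tcr$cell_id, tcr$locus), ]
  rownames(tcr) <- NULL
  clo <- setNames(clonotype_id, cell_id)
  clo[drop_a | drop_b] <- NA_character_
  list(tcr = tcr, clonotype = clo)
}

assemble_dataset <- function(config, panel, pools, parts) {
  gene <- Matrix::Matrix(do.call(rbind, lapply(parts, `[[`, "gene")),
                         sparse = TRUE)
  adt <- do.call(rbind, lapply(parts, `[[`, "adt"))
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  rownames(meta) <- NULL
  tcr <- do.call(rbind, lapply(parts, `[[`, "tcr"))
  rownames(tcr) <- NULL
  clonotype <- do.call(c, lapply(parts, `[[`, "clonotype"))

  bg <- matrix(rpois(config$n_empty_droplets * length(panel$adt_names),
                     rep(panel$ambient, each = config$n_empty_droplets)),
               config$n_empty_droplets,
               dimnames = list(sprintf("empty%04d",
                                       seq_len(config$n_empty_droplets)),
                               panel$adt_names))

  structure(
    list(
      gene_counts = gene, adt_counts = adt, adt_background = bg,
      cell_meta = meta, tcr = tcr,
      isotype_names = config$feature_names$isotypes,
      truth = list(
        planted_de = config$planted_de,
        subset_markers = list(genes = panel$subset_genes,
                              adts = panel$subset_adts),
        state_markers = panel$state_genes,
        clonotype = clonotype,
        pools = pools,
        base_mean = panel$base_mean
      ),
      config = config
    ),
    class = "icisig_dataset"
  )
}

#' @export
print.icisig_dataset <- function(x, ...) {
  cat(sprintf("icisig dataset: %d cells x %d genes, %d ADT markers\n",
              nrow(x$gene_counts), ncol(x$gene_counts), ncol(x$adt_counts)))
  cat(sprintf("  %d samples from %d donors; groups: %s\n",
              length(unique(x$cell_meta$sample_id)),
              length(unique(x$cell_meta$donor_id)),
              paste(unique(x$cell_meta$response_group), collapse = ", ")))
  invisible(x)
}

#' Simulate a two-visit sample pair with controlled clonotype sharing
#'
#' Generates two longitudinal samples (visits v1 and v2) of a single donor
#' from the first response group of `config`. A configurable fraction of the
#' v1 clonotypes persists into v2; persisting clonotypes have their v2
#' frequency scaled by `expansion_factor` before renormalization, emulating
#' longitudinal clonal expansion.
#'
#' @param config an [sim_config()] object (donor/visit counts are ignored;
#'   one donor, two visits are generated).
#' @param shared_fraction fraction of v1 clonotypes carried into v2, in
#'   \[0, 1\].
#' @param expansion_factor multiplicative change of shared clonotypes'
#'   normalized size at v2; must be positive.
#' @return An `icisig_dataset` holding the two samples, with attributes
#'   `sample_v1` and `sample_v2` naming them.
#' @export
simulate_timepoint_pair <- function(config, shared_fraction,
                                    expansion_factor = 1) {
  stopifnot(inherits(config, "icisig_sim_config"))
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop_cfg("`shared_fraction` must lie in [0, 1]")
  }
  if (!is.numeric(expansion_factor) || expansion_factor <= 0) {
    stop_cfg("`expansion_factor` must be positive")
  }
  group <- config$groups[1]
  donor_id <- sprintf("%s01", group)
  with_seed(config$seed, {
    panel <- sim_panel(config)
    pools <- sim_tcr_pools(config)
    v1 <- gen_sample(config, panel, pools, paste0(donor_id, "_v1"), donor_id,
                     group, 1L)

    # v1 clone composition (paired cells only)
    ok <- !is.na(v1$clonotype)
    tab <- table(v1$clonotype[ok])
    ids1 <- names(tab)
    sizes1 <- as.numeric(tab) / sum(tab)
    keep <- sample(length(ids1), round(shared_fraction * length(ids1)))

    # rebuild the clonotype records of the kept clones from v1's TCR rows
    ct1 <- clonotype_records_from(v1$tcr, v1$clonotype)
    shared_ids <- ids1[keep]
    w_shared <- sizes1[keep] * expansion_factor

    n_new <- length(ids1) - length(keep)
    v1_keys <- do.call(paste, ct1[, c("cdr3a", "va", "ja", "cdr3b", "vb",
                                      "jb")])
    new <- vector("list", max(n_new, 0))
    for (i in seq_len(max(n_new, 0))) {
      # reject draws colliding with a v1 clonotype so non-persisting
      # clonotypes are genuinely new
      repeat {
        cand <- draw_clonotype(config, pools[[group]])
        if (!do.call(paste, cand$clonotype) %in% v1_keys) break
      }
      new[[i]] <- cand
    }
    w_new <- if (n_new > 0) rep((1 - sum(sizes1[keep])) / n_new, n_new)
             else numeric()
    cts <- rbind(ct1[match(shared_ids, ct1$clonotype_id),
                     c("cdr3a", "va", "ja", "cdr3b", "vb", "jb")],
                 do.call(rbind, lapply(new, function(x) x$clonotype)))
    clone_ids <- c(shared_ids, vapply(new, `[[`, character(1), "id"))
    w <- c(w_shared, w_new)
    if (sum(w) <= 0) w <- rep(1, length(w))
    # every persisting clonotype is guaranteed one v2 cell so the realized
    # shared fraction tracks `shared_fraction`; remaining cells fall
    # multinomially on the expansion-scaled weights
    n2 <- config$cells_per_sample
    wn <- w / sum(w)
    guaranteed <- integer(length(clone_ids))
    n_shared <- length(shared_ids)
    if (n_shared > 0) guaranteed[seq_len(min(n_shared, n2))] <- 1L
    rest <- n2 - sum(guaranteed)
    # remaining cells fall on the weights net of the guaranteed cell, so the
    # expected total per clonotype still tracks its (expansion-scaled) weight
    w_rest <- pmax(wn - guaranteed / n2, 0)
    if (sum(w_rest) <= 0) w_rest <- wn
    assign_counts <- guaranteed +
      if (rest > 0) as.vector(rmultinom(1, rest, w_rest / sum(w_rest)))
      else 0L
    clone_per_cell <- rep(seq_along(clone_ids), assign_counts)
    subset_per_cell <- sample(config$subset_names, length(clone_per_cell),
                              replace = TRUE,
                              prob = config$subset_props_by_group[group, ])
    plan <- list(clonotypes = cts, clone_ids = clone_ids,
                 clone_per_cell = clone_per_cell,
                 subset_per_cell = subset_per_cell)
    v2 <- gen_sample(config, panel, pools, paste0(donor_id, "_v2"), donor_id,
                     group, 2L, clone_plan = plan)
    ds <- assemble_dataset(config, panel, pools, list(v1, v2))
    attr(ds, "sample_v1") <- paste0(donor_id, "_v1")
    attr(ds, "sample_v2") <- paste0(donor_id, "_v2")
    ds
  })
}

# Reconstruct one clonotype record per clone id from long TCR records.
clonotype_records_from <- function(tcr, clonotype_per_cell) {
  ok <- !is.na(clonotype_per_cell)
  cells <- names(clonotype_per_cell)[ok]
  first <- cells[!duplicated(clonotype_per_cell[ok])]
  ids <- clonotype_per_cell[first]
  a <- tcr[tcr$locus == "TRA", ]
  b <- tcr[tcr$locus == "TRB", ]
  b <- b[!duplicated(b$cell_id), ] # ignore extra beta chains here
  ia <- match(first, a$cell_id)
  ib <- match(first, b$cell_id)
  data.frame(
    clonotype_id = ids,
    cdr3a = a$junction_aa[ia], va = a$v_call[ia], ja = a$j_call[ia],
    cdr3b = b$junction_aa[ib], vb = b$v_call[ib], jb = b$j_call[ib],
    stringsAsFactors = FALSE
  )
}
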