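#' Configuration for a simulated CITE-seq + paired-TCR cohort
#'
#' Builds and validates the parameter set describing a synthetic multi-donor
#' cohort of blood CD8+ T cells with two response groups (long-term
#' responders, `LTR`, and non-responders, `NonR`). The generator plants
#' known group effects (differential features, subset composition shifts,
#' group-structured TCR sharing) so that every downstream stage of the
#' pipeline can be checked against ground truth.
#'
#' Subset proportions default to a cohort in which naive T cells (TN) are
#' depleted and effector memory cells (TEM) enriched in responders, the
#' composition trend reported for checkpoint-inhibitor responders. Clone
#' sizes are geometric with a subset-specific success probability that
#' decreases with T-cell maturity (TN < TSCM < TCM < TEM < TEMRA), so
#' expected clone size grows as cells differentiate; this ordering is
#' enforced at validation time.
#'
#' @param n_donors_per_group named integer vector, donors per response group
#'   (names are the group labels; first group is the baseline/numerator in
#'   downstream comparisons).
#' @param visits_per_donor number of longitudinal samples per donor; each
#'   (donor, visit) pair is one sample.
#' @param cells_per_sample cells simulated per sample.
#' @param n_genes total RNA features, including mitochondrial/ribosomal genes.
#' @param n_adt surface markers excluding isotype controls.
#' @param n_isotype_controls isotype-control ADT rows (ambient-only).
#' @param subset_names T-cell subset labels, ordered by maturity where
#'   applicable.
#' @param subset_props_by_group matrix (group x subset) of subset
#'   probabilities; rows must sum to 1.
#' @param planted_de `NULL` or data.frame with columns `subset`, `feature`,
#'   `group`, `log2fc`: cells of that subset and group get the feature's mean
#'   multiplied by `2^log2fc`.
#' @param clone_size_shape named vector of geometric success probabilities
#'   per subset (smaller = larger clones); must be non-increasing along the
#'   maturity order TN, TSCM, TCM, TEM, TEMRA.
#' @param tcr_group_sharing probability that a clonotype is drawn from the
#'   group-shared motif pool rather than generated privately.
#' @param tcr_pool_size number of motif centroids in each group's shared pool.
#' @param ambient_adt_mean Poisson mean of ambient ADT background, scalar or
#'   one value per marker (isotypes included).
#' @param adt_signal_mean baseline signal mean of a surface marker on a cell
#'   (before subset-marker elevation and planted effects).
#' @param adt_dispersion negative-binomial dispersion of the ADT cell signal;
#'   protein counts are overdispersed relative to Poisson.
#' @param depth_mean expected RNA library size of a cell.
#' @param depth_sdlog sdlog of the per-sample lognormal depth multiplier.
#' @param nb_dispersion negative-binomial dispersion shared by all genes
#'   (`size = 1/dispersion`).
#' @param n_mito_genes,n_ribo_genes number of "MT-"- and "RPS"/"RPL"-prefixed
#'   genes in the panel, so mitochondrial/ribosomal QC percentages are
#'   computable.
#' @param mito_frac,ribo_frac expected fraction of a cell's UMIs on
#'   mitochondrial and ribosomal genes.
#' @param n_subset_marker_genes,n_subset_marker_adts markers planted per
#'   subset (recorded in the returned dataset's truth slot).
#' @param marker_log2fc elevation of a subset's own markers, log2 scale.
#' @param state_names cell-state labels.
#' @param state_props probability vector over states (shared by both groups
#'   and all subsets).
#' @param n_state_marker_genes,state_marker_log2fc state-marker planting.
#' @param frac_unpaired fraction of cells carrying only one TCR chain.
#' @param frac_multi_beta fraction of cells carrying two beta chains
#'   (dropped by clonotype construction, exercised in tests).
#' @param n_empty_droplets ambient-only ADT barcodes emitted alongside the
#'   cells, used as the background set for ADT normalization.
#' @param seed integer RNG seed; identical configurations with identical
#'   seeds yield bit-identical datasets.
#'
#' @return An object of class `icisig_sim_config` (a validated list).
#' @seealso [simulate_dataset()], [simulate_timepoint_pair()]
#' @export
sim_config <- function(n_donors_per_group = c(LTR = 8L, NonR = 6L),
                       visits_per_donor = 1L,
                       cells_per_sample = 200L,
                       n_genes = 1000L,
                       n_adt = 30L,
                       n_isotype_controls = 3L,
                       subset_names = c("TN", "TSCM", "TCM", "TEM", "TEMRA",
                                        "MAIT", "NKT-like"),
                       subset_props_by_group = NULL,
                       planted_de = NULL,
                       clone_size_shape = NULL,
                       tcr_group_sharing = 0.5,
                       tcr_pool_size = 10L,
                       ambient_adt_mean = 5,
                       adt_signal_mean = 20,
                       adt_dispersion = 0.5,
                       depth_mean = 2000,
                       depth_sdlog = 0.3,
                       nb_dispersion = 0.5,
                       n_mito_genes = 10L,
                       n_ribo_genes = 20L,
                       mito_frac = 0.03,
                       ribo_frac = 0.30,
                       n_subset_marker_genes = 5L,
                       n_subset_marker_adts = 2L,
                       marker_log2fc = 3,
                       state_names = c("resting", "activated", "cytotoxic",
                                       "exhausted"),
                       state_props = c(0.35, 0.25, 0.25, 0.15),
                       n_state_marker_genes = 3L,
                       state_marker_log2fc = 2,
                       frac_unpaired = 0.05,
                       frac_multi_beta = 0.01,
                       n_empty_droplets = 300L,
                       seed = 1L) {
  groups <- names(n_donors_per_group)
  if (is.null(groups) || any(!nzchar(groups)) || anyDuplicated(groups)) {
    stop_cfg("`n_donors_per_group` must be a uniquely named vector of counts")
  }
  for (v in n_donors_per_group) {
    if (!is_count(v, min = 1L)) stop_cfg("donor counts must be positive integers")
  }
  if (!is_count(visits_per_donor, 1L)) stop_cfg("`visits_per_donor` must be >= 1")
  for (nm in c("cells_per_sample", "n_genes", "n_adt")) {
    if (!is_count(get(nm), 1L)) stop_cfg("`", nm, "` must be a positive integer")
  }
  if (!is_count(n_isotype_controls, 1L)) {
    stop_cfg("at least one isotype control is required")
  }
  if (anyDuplicated(subset_names)) stop_cfg("subset names must be unique")
  n_sub <- length(subset_names)

  if (is.null(subset_props_by_group)) {
    subset_props_by_group <- default_subset_props(groups, subset_names)
  }
  subset_props_by_group <- as.matrix(subset_props_by_group)
  if (!identical(dim(subset_props_by_group), c(length(groups), n_sub)) ||
      !identical(rownames(subset_props_by_group), groups) ||
      !identical(colnames(subset_props_by_group), subset_names)) {
    stop_cfg("`subset_props_by_group` must be a group x subset matrix with ",
             "matching dimnames")
  }
  if (any(subset_props_by_group < 0) ||
      any(abs(rowSums(subset_props_by_group) - 1) > 1e-9)) {
    stop_cfg("subset proportions must be nonnegative and sum to 1 per group")
  }
  if (abs(sum(state_props) - 1) > 1e-9 || any(state_props < 0) ||
      length(state_props) != length(state_names)) {
    stop_cfg("`state_props` must be a probability vector over `state_names`")
  }

  if (is.null(clone_size_shape)) {
    clone_size_shape <- default_clone_shape(subset_names)
  }
  if (is.null(names(clone_size_shape)) ||
      !setequal(names(clone_size_shape), subset_names)) {
    stop_cfg("`clone_size_shape` needs one value per subset")
  }
  clone_size_shape <- clone_size_shape[subset_names]
  if (any(clone_size_shape <= 0) || any(clone_size_shape > 1)) {
    stop_cfg("geometric success probabilities must lie in (0, 1]")
  }
  maturity <- c("TN", "TSCM", "TCM", "TEM", "TEMRA")
  present <- maturity[maturity %in% subset_names]
  if (length(present) > 1 && any(diff(clone_size_shape[present]) > 1e-12)) {
    stop_cfg("clone-size success probability must be non-increasing with ",
             "subset maturity (", paste(present, collapse = " < "), ")")
  }

  if (n_mito_genes + n_ribo_genes >= n_genes) {
    stop_cfg("mitochondrial + ribosomal genes must leave room for other genes")
  }
  if (tcr_group_sharing < 0 || tcr_group_sharing > 1) {
    stop_cfg("`tcr_group_sharing` must be a probability")
  }
  if (!is_count(seed) && !is_count(-seed)) stop_cfg("`seed` must be an integer")

  feats <- feature_names(n_genes, n_mito_genes, n_ribo_genes, n_adt,
                         n_isotype_controls)
  if (!is.null(planted_de)) {
    planted_de <- as.data.frame(planted_de)
    need <- c("subset", "feature", "group", "log2fc")
    if (!all(need %in% names(planted_de))) {
      stop_cfg("`planted_de` needs columns ", paste(need, collapse = ", "))
    }
    if (!all(planted_de$subset %in% subset_names)) {
      stop_cfg("planted_de refers to unknown subset(s)")
    }
    if (!all(planted_de$group %in% groups)) {
      stop_cfg("planted_de refers to unknown group(s)")
    }
    if (any(planted_de$feature %in% feats$isotypes)) {
      stop_cfg("planted effects on isotype controls are not allowed")
    }
    known <- c(feats$genes, feats$adt)
    if (!all(planted_de$feature %in% known)) {
      stop_cfg("planted_de refers to feature(s) absent from the panel")
    }
  }

  structure(
    list(
      n_donors_per_group = n_donors_per_group,
      groups = groups,
      visits_per_donor = as.integer(visits_per_donor),
      cells_per_sample = as.integer(cells_per_sample),
      n_genes = as.integer(n_genes),
      n_adt = as.integer(n_adt),
      n_isotype_controls = as.integer(n_isotype_controls),
      subset_names = subset_names,
      subset_props_by_group = subset_props_by_group,
      planted_de = planted_de,
      clone_size_shape = clone_size_shape,
      tcr_group_sharing = tcr_group_sharing,
      tcr_pool_size = as.integer(tcr_pool_size),
      ambient_adt_mean = ambient_adt_mean,
      adt_signal_mean = adt_signal_mean,
      adt_dispersion = adt_dispersion,
      depth_mean = depth_mean,
      depth_sdlog = depth_sdlog,
      nb_dispersion = nb_dispersion,
      n_mito_genes = as.integer(n_mito_genes),
      n_ribo_genes = as.integer(n_ribo_genes),
      mito_frac = mito_frac,
      ribo_frac = ribo_frac,
      n_subset_marker_genes = as.integer(n_subset_marker_genes),
      n_subset_marker_adts = as.integer(n_subset_marker_adts),
      marker_log2fc = marker_log2fc,
      state_names = state_names,
      state_props = state_props,
      n_state_marker_genes = as.integer(n_state_marker_genes),
      state_marker_log2fc = state_marker_log2fc,
      frac_unpaired = frac_unpaired,
      frac_multi_beta = frac_multi_beta,
      n_empty_droplets = as.integer(n_empty_droplets),
      feature_names = feats,
      seed = as.integer(seed)
    ),
    class = "icisig_sim_config"
  )
}

# Composition defaults: TN depleted / TEM enriched in the first (responder)
# group relative to the second; additional groups reuse the second group's row.
default_subset_props <- function(groups, subset_names) {
  base <- list(
    resp = c(TN = 0.10, TSCM = 0.10, TCM = 0.14, TEM = 0.31, TEMRA = 0.20,
             MAIT = 0.10, `NKT-like` = 0.05),
    nonr = c(TN = 0.22, TSCM = 0.12, TCM = 0.16, TEM = 0.25, TEMRA = 0.12,
             MAIT = 0.08, `NKT-like` = 0.05)
  )
  if (!setequal(subset_names, names(base$resp))) {
    # non-default panel: uniform proportions for every group
    m <- matrix(1 / length(subset_names), length(groups), length(subset_names),
                dimnames = list(groups, subset_names))
    return(m)
  }
  rows <- lapply(seq_along(groups), function(i) {
    if (i == 1) base$resp[subset_names] else base$nonr[subset_names]
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(groups, subset_names)
  m
}

default_clone_shape <- function(subset_names) {
  defaults <- c(TN = 0.95, TSCM = 0.90, TCM = 0.80, TEM = 0.60, TEMRA = 0.40,
                MAIT = 0.70, `NKT-like` = 0.60)
  out <- setNames(rep(0.8, length(subset_names)), subset_names)
  hit <- intersect(subset_names, names(defaults))
  out[hit] <- defaults[hit]
  out
}

feature_names <- function(n_genes, n_mito, n_ribo, n_adt, n_iso) {
  mito <- sprintf("MT-G%d", seq_len(n_mito))
  half <- ceiling(n_ribo / 2)
  ribo <- c(sprintf("RPS%d", seq_len(half)),
            sprintf("RPL%d", seq_len(n_ribo - half)))
  other <- sprintf("GENE%04d", seq_len(n_genes - n_mito - n_ribo))
  adt <- sprintf("ADT%03d", seq_len(n_adt))
  iso <- sprintf("isotype%d", seq_len(n_iso))
  list(genes = c(mito, ribo, other), mito = mito, ribo = ribo, other = other,
       adt = adt, isotypes = iso)
}

#' @export
print.icisig_sim_config <- function(x, ...) {
  n_samp <- sum(x$n_donors_per_group) * x$visits_per_donor
  cat("icisig simulation config\n")
  cat("  groups: ",
      paste(sprintf("%s (%d donors)", x$groups, x$n_donors_per_group),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d samples x %d cells, %d genes, %d ADT (+%d isotype)\n",
              n_samp, x$cells_per_sample, x$n_genes, x$n_adt,
              x$n_isotype_controls))
  cat(sprintf("  planted effects: %d, seed %d\n",
              if (is.null(x$planted_de)) 0L else nrow(x$planted_de), x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param config an `icisig_sim_config`.
#' @param path file path.
#' @return `read_sim_config()` returns a validated `icisig_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "icisig_sim_config"))
  x <- unclass(config)
  x$feature_names <- NULL
  x$groups <- NULL
  x$subset_props_by_group <- lapply(
    setNames(rownames(config$subset_props_by_group),
             rownames(config$subset_props_by_group)),
    function(g) as.list(config$subset_props_by_group[g, ])
  )
  x$clone_size_shape <- as.list(config$clone_size_shape)
  x$n_donors_per_group <- as.list(config$n_donors_per_group)
  if (!is.null(x$planted_de)) {
    x$planted_de <- lapply(seq_len(nrow(config$planted_de)), function(i) {
      as.list(config$planted_de[i, c("subset", "feature", "group", "log2fc")])
    })
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  groups <- names(x$n_donors_per_group)
  x$n_donors_per_group <- setNames(unlist(x$n_donors_per_group), groups)
  subsets <- unique(unlist(lapply(x$subset_props_by_group, names)))
  props <- do.call(rbind, lapply(x$subset_props_by_group, function(r) {
    unlist(r)[subsets]
  }))
  dimnames(props) <- list(names(x$subset_props_by_group), subsets)
  x$subset_props_by_group <- props
  x$subset_names <- subsets
  x$clone_size_shape <- unlist(x$clone_size_shape)
  if (!is.null(x$planted_de)) {
    x$planted_de <- do.call(rbind, lapply(x$planted_de, as.data.frame))
  }
  do.call(sim_config, x)
}
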