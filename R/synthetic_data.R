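# Synthetic single-cell / bulk / survival data with planted ground truth:
# multiple cell types, a TF-driven regulon active in a myeloid subpopulation,
# responder vs nonresponder samples, doublets, and QC gene classes.

SIM_CELL_TYPES <- c("T", "B", "myeloid", "epithelial")

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions the workflow targets: a tumour
#' microenvironment with T/B/myeloid/epithelial cells where responders carry
#' both a larger myeloid compartment (19.0% vs 11.8%) and a larger fraction
#' of regulon-active myeloid cells (0.6 vs 0.1), the regulon being the
#' packaged 23-target PPARG set boosted 4-fold (regulon_effect 3) in active
#' cells. Droplet doublets occur at rate 0.025.
#'
#' @param n_genes number of genes (>= 150; includes mitochondrial,
#'   ribosomal, housekeeping, lineage-marker and regulon genes).
#' @param n_cells_per_sample cells per sample before QC.
#' @param n_samples_per_group samples (subjects) per response group.
#' @param myeloid_fraction_responder,myeloid_fraction_nonresponder expected
#'   myeloid fraction per group, in (0,1).
#' @param active_fraction_within_myeloid named numeric
#'   `c(responder=, nonresponder=)`: fraction of myeloid cells in the
#'   regulon-active state.
#' @param regulon_effect multiplicative boost minus one applied to the TF and
#'   target-gene means in regulon-active cells (mean x (1 + regulon_effect)).
#' @param doublet_rate fraction of droplets that are doublets, in [0,1).
#' @param nb_dispersion negative-binomial size parameter shared by all genes.
#' @param mito_gene_count,ribo_gene_count number of `MT-` and `RPS`/`RPL`
#'   genes in the universe.
#' @param mean_mito,mean_ribo,mean_housekeeping,mean_marker,mean_filler
#'   base mean UMI counts of the gene classes (all cell types).
#' @param mean_target_myeloid,mean_target_other base mean of the regulon
#'   target genes in myeloid vs non-myeloid cells.
#' @param cell_type_profiles optional genes x 4 matrix of mean expression
#'   (columns T, B, myeloid, epithelial) overriding the built-in universe;
#'   must carry rownames.
#' @param universe_seed seed fixing the filler-gene mean draw; shared across
#'   cohorts by default so that independently seeded simulations describe the
#'   same gene universe (as real cohorts share a genome).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_cells_per_sample = 400L,
                             n_samples_per_group = 2L,
                             myeloid_fraction_responder = 0.19,
                             myeloid_fraction_nonresponder = 0.118,
                             active_fraction_within_myeloid =
                               c(responder = 0.6, nonresponder = 0.1),
                             regulon_effect = 3,
                             doublet_rate = 0.025,
                             nb_dispersion = 2,
                             mito_gene_count = 13L,
                             ribo_gene_count = 80L,
                             mean_mito = 8, mean_ribo = 2,
                             mean_housekeeping = 50, mean_marker = 20,
                             mean_filler = 0.5,
                             mean_target_myeloid = 2,
                             mean_target_other = 0.5,
                             cell_type_profiles = NULL,
                             universe_seed = 777L,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_sample = as.integer(n_cells_per_sample),
              n_samples_per_group = as.integer(n_samples_per_group),
              myeloid_fraction_responder = myeloid_fraction_responder,
              myeloid_fraction_nonresponder = myeloid_fraction_nonresponder,
              active_fraction_within_myeloid = active_fraction_within_myeloid,
              regulon_effect = regulon_effect,
              doublet_rate = doublet_rate,
              nb_dispersion = nb_dispersion,
              mito_gene_count = as.integer(mito_gene_count),
              ribo_gene_count = as.integer(ribo_gene_count),
              mean_mito = mean_mito, mean_ribo = mean_ribo,
              mean_housekeeping = mean_housekeeping,
              mean_marker = mean_marker, mean_filler = mean_filler,
              mean_target_myeloid = mean_target_myeloid,
              mean_target_other = mean_target_other,
              cell_type_profiles = cell_type_profiles,
              housekeeping_genes = c("ACTB", "GAPDH", "MALAT1"),
              universe_seed = as.integer(universe_seed),
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  assert_scalar_number(cfg$n_genes, "n_genes", lower = 150)
  assert_scalar_number(cfg$n_cells_per_sample, "n_cells_per_sample", lower = 1)
  assert_scalar_number(cfg$n_samples_per_group, "n_samples_per_group", lower = 1)
  assert_scalar_number(cfg$myeloid_fraction_responder,
                       "myeloid_fraction_responder", 0, 1,
                       lower_open = TRUE, upper_open = TRUE)
  assert_scalar_number(cfg$myeloid_fraction_nonresponder,
                       "myeloid_fraction_nonresponder", 0, 1,
                       lower_open = TRUE, upper_open = TRUE)
  af <- cfg$active_fraction_within_myeloid
  if (!all(c("responder", "nonresponder") %in% names(af))) {
    stopf("active_fraction_within_myeloid must be named (responder, nonresponder)")
  }
  for (nm in c("responder", "nonresponder")) {
    assert_scalar_number(af[[nm]], paste0("active_fraction[", nm, "]"), 0, 1)
  }
  assert_scalar_number(cfg$regulon_effect, "regulon_effect", lower = 0)
  assert_scalar_number(cfg$doublet_rate, "doublet_rate", 0, 1, upper_open = TRUE)
  assert_scalar_number(cfg$nb_dispersion, "nb_dispersion", lower = 0,
                       lower_open = TRUE)
  if (!is.null(cfg$cell_type_profiles)) {
    p <- cfg$cell_type_profiles
    if (nrow(p) != cfg$n_genes || is.null(rownames(p)) ||
        !identical(colnames(p), SIM_CELL_TYPES)) {
      stopf("cell_type_profiles must be n_genes x 4 with rownames and columns %s",
            paste(SIM_CELL_TYPES, collapse = ", "))
    }
  }
  invisible(cfg)
}

#' Read a generator configuration from a JSON file
#'
#' @param path JSON file whose keys are `synthetic_config()` arguments.
#' @return a `SyntheticConfig`.
#' @export
read_synthetic_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(args), names(formals(synthetic_config)))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(synthetic_config, args)
}

# Gene universe + per-type mean profiles. Mito/ribo/housekeeping classes and
# lineage markers are planted so every QC rule and the marker gate have
# ground truth; the PPARG regulon reuses the packaged 23 target names.
build_profiles <- function(cfg) {
  if (!is.null(cfg$cell_type_profiles)) return(cfg$cell_type_profiles)
  hk <- cfg$housekeeping_genes
  mito <- sprintf("MT-%d", seq_len(cfg$mito_gene_count))
  nr <- cfg$ribo_gene_count
  ribo <- c(sprintf("RPS%d", seq_len(ceiling(nr / 2))),
            sprintf("RPL%d", seq_len(floor(nr / 2))))
  sigs <- lineage_signatures()
  markers <- lapply(sigs, function(s) s$targets)
  targets <- pparg_regulon()$targets
  named <- c(hk, mito, ribo, unlist(markers, use.names = FALSE),
             "FCER1A", "PPARG", targets)
  stopifnot(!anyDuplicated(named))
  n_fill <- cfg$n_genes - length(named)
  if (n_fill < 0) stopf("n_genes = %d too small for the %d named genes",
                        cfg$n_genes, length(named))
  fill <- sprintf("G%04d", seq_len(n_fill))
  genes <- c(named, fill)

  prof <- matrix(0, length(genes), length(SIM_CELL_TYPES),
                 dimnames = list(genes, SIM_CELL_TYPES))
  prof[hk, ] <- cfg$mean_housekeeping
  prof[mito, ] <- cfg$mean_mito
  prof[ribo, ] <- cfg$mean_ribo
  # filler means: a log-normal draw keyed to the universe seed, which is
  # shared across cohorts by default -- all simulations inhabit the same
  # "genome", only the cell sampling varies with the config seed
  fill_means <- with_seed(derive_seed(cfg$universe_seed, "universe"),
                          exp(rnorm(n_fill, log(cfg$mean_filler), 0.6)))
  prof[fill, ] <- fill_means
  for (ty in SIM_CELL_TYPES) {
    own <- markers[[ty]]
    prof[own, ] <- 0.05
    prof[own, ty] <- cfg$mean_marker
  }
  # FCER1A (dendritic/B marker): expressed outside the monocyte lineage
  prof["FCER1A", ] <- 6
  prof["FCER1A", "myeloid"] <- 0.02
  prof["PPARG", ] <- 0.2
  prof["PPARG", "myeloid"] <- 1
  prof[targets, ] <- cfg$mean_target_other
  prof[targets, "myeloid"] <- cfg$mean_target_myeloid
  prof
}

# Genes whose means are boosted in regulon-active cells (TF + targets).
regulon_gene_rows <- function() c("PPARG", pparg_regulon()$targets)

# Draw NB counts for a block of cells given a genes x cells mean matrix.
draw_counts <- function(mu, size) {
  matrix(rnbinom(length(mu), size = size, mu = as.vector(mu)),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

# Singlet state draws for one sample: type + active flag + mean matrix.
sample_singlets <- function(cfg, prof, group, n) {
  myl <- if (group == "responder") cfg$myeloid_fraction_responder else
    cfg$myeloid_fraction_nonresponder
  act <- cfg$active_fraction_within_myeloid[[group]]
  other <- c(T = 0.5, B = 0.2, epithelial = 0.3) * (1 - myl)
  p <- c(other["T"], other["B"], myeloid = myl, other["epithelial"])
  type <- sample(SIM_CELL_TYPES[c(1, 2, 3, 4)], n, replace = TRUE,
                 prob = p[c("T", "B", "myeloid", "epithelial")])
  active <- type == "myeloid" & runif(n) < act
  mu <- prof[, type, drop = FALSE]
  if (any(active)) {
    rg <- regulon_gene_rows()
    mu[rg, active] <- mu[rg, active] * (1 + cfg$regulon_effect)
  }
  list(type = type, active = active, mu = mu)
}

#' Simulate a single-cell UMI cohort with planted ground truth
#'
#' Draws negative-binomial counts around per-type mean profiles for
#' responder and nonresponder samples. Regulon-active myeloid cells have the
#' TF and target means multiplied by `1 + regulon_effect`; myeloid profiles
#' are CD14-high / FCER1A-low; a `doublet_rate` fraction of droplets are raw
#' count sums of two singlet draws. Ground truth (`celltype`,
#' `regulon_active`, `is_doublet`) is recorded in `cell_meta`.
#'
#' @param config a `SyntheticConfig`.
#' @return a `CellMatrix`; deterministic given the config seed.
#' @export
simulate_cells <- function(config) {
  validate_config(config)
  prof <- build_profiles(config)
  with_seed(derive_seed(config$seed, "cells"), {
    blocks <- list(); metas <- list()
    for (group in c("responder", "nonresponder")) {
      for (s in seq_len(config$n_samples_per_group)) {
        sid <- sprintf("%s%d", if (group == "responder") "R" else "N", s)
        n <- config$n_cells_per_sample
        n_dbl <- round(config$doublet_rate * n)
        n_sgl <- n - n_dbl
        st <- sample_singlets(config, prof, group, n_sgl)
        counts <- draw_counts(st$mu, config$nb_dispersion)
        type <- st$type; active <- st$active; dbl <- rep(FALSE, n_sgl)
        if (n_dbl > 0) {
          pa <- sample_singlets(config, prof, group, n_dbl)
          pb <- sample_singlets(config, prof, group, n_dbl)
          dcounts <- draw_counts(pa$mu, config$nb_dispersion) +
            draw_counts(pb$mu, config$nb_dispersion)
          counts <- cbind(counts, dcounts)
          type <- c(type, pa$type)           # doublets inherit the label of
          active <- c(active, pa$active)     # their first component
          dbl <- c(dbl, rep(TRUE, n_dbl))
        }
        colnames(counts) <- sprintf("%s_c%04d", sid, seq_len(ncol(counts)))
        blocks[[sid]] <- counts
        metas[[sid]] <- data.frame(
          cell_id = colnames(counts), sample_id = sid,
          timepoint = if (group == "responder") "post" else "pre",
          response = group, celltype = type, cluster = NA_integer_,
          regulon_active = active, is_doublet = dbl,
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, blocks)
    meta <- do.call(rbind, metas)
    rownames(meta) <- NULL
    cell_matrix(counts, cell_meta = meta)
  })
}

#' Simulate pseudo-bulk samples with linked survival outcomes
#'
#' Each bulk sample is the column sum of `n_cells_pooled` simulated singlet
#' cells from one synthetic subject (responder or nonresponder composition,
#' no doublets). Survival time is exponential with a hazard that decreases
#' with the subject's realized fraction of regulon-active cells: the hazard
#' ratio between the nonresponder and responder design points is
#' `harm_ratio`. Censoring is independent exponential plus an
#' administrative cut at `max_followup` months.
#'
#' @param config a `SyntheticConfig` (`n_samples_per_group` subjects per group).
#' @param n_cells_pooled cells summed per subject (>= 1).
#' @param harm_ratio hazard ratio across the design range of the
#'   regulon-active fraction; 1 means survival is unlinked.
#' @param base_hazard hazard (1/months) at the nonresponder design point.
#' @param censor_hazard hazard of the independent censoring process.
#' @param max_followup administrative censoring time in months.
#' @return a `BulkMatrix` whose `sample_meta` carries `response`, realized
#'   `active_fraction`, `time` and `event`.
#' @export
simulate_bulk <- function(config, n_cells_pooled = 100L, harm_ratio = 3,
                          base_hazard = log(2) / 12,
                          censor_hazard = log(2) / 40, max_followup = 60) {
  validate_config(config)
  if (n_cells_pooled < 1) stopf("n_cells_pooled must be >= 1")
  assert_scalar_number(harm_ratio, "harm_ratio", lower = 0, lower_open = TRUE)
  prof <- build_profiles(config)
  f_R <- config$myeloid_fraction_responder *
    config$active_fraction_within_myeloid[["responder"]]
  f_N <- config$myeloid_fraction_nonresponder *
    config$active_fraction_within_myeloid[["nonresponder"]]
  with_seed(derive_seed(config$seed, "bulk"), {
    cols <- list(); meta <- list()
    for (group in c("responder", "nonresponder")) {
      for (s in seq_len(config$n_samples_per_group)) {
        sid <- sprintf("bulk_%s%d", if (group == "responder") "R" else "N", s)
        st <- sample_singlets(config, prof, group, n_cells_pooled)
        counts <- draw_counts(st$mu, config$nb_dispersion)
        f_i <- mean(st$active)
        z <- if (abs(f_R - f_N) < .Machine$double.eps) 0 else (f_i - f_N) / (f_R - f_N)
        hazard <- base_hazard * harm_ratio^(-z)
        t_event <- rexp(1, hazard)
        t_cens <- min(rexp(1, censor_hazard), max_followup)
        cols[[sid]] <- rowSums(counts)
        meta[[sid]] <- data.frame(
          sample_id = sid, response = group, active_fraction = f_i,
          time = max(min(t_event, t_cens), 1e-3),
          event = as.integer(t_event <= t_cens),
          immune_score = NA_real_, stringsAsFactors = FALSE)
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- rownames(prof)
    bulk_matrix(values, do.call(rbind, meta))
  })
}
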