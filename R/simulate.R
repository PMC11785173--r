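#' Simulation configuration for planted gene-program-trait structures
#'
#' Defines the ground-truth structure (programs, their regulators and member
#' genes, trait weights) and the observation model (burden-test noise,
#' single-cell depth and batching) for the synthetic-data generator. Defaults
#' mirror a genome-wide CRISPRi screen in an erythroid cell line: a median of
#' 166 cells per gene perturbation and roughly 11,500 UMIs per cell.
#'
#' @param n_genes number of genes in the universe.
#' @param n_programs number of co-expression programs K.
#' @param n_regulators_per_program regulators planted per program (disjoint
#'   across programs and from member genes).
#' @param n_member_genes_per_program member (content) genes per program.
#' @param regulator_effect_scale typical magnitude of a planted regulatory
#'   effect beta (usage units per knockdown).
#' @param content_weight_per_program numeric vector (length `n_programs`):
#'   trait contribution shared by every member gene of a program.
#' @param regulator_path_weight_per_program numeric vector (length
#'   `n_programs`): weight w_p of the regulator path program -> trait.
#' @param trait_noise_sd standard deviation of the gene-level trait noise
#'   added to the structural gamma.
#' @param se_range length-2 numeric, low < high: range of burden-test
#'   standard errors.
#' @param shet_gamma_coupling Gaussian-copula correlation in `[0,1]` between
#'   shet and `|gamma_true|` (constrained genes tend to larger trait effects).
#' @param n_cells_per_perturbation cells per perturbed gene.
#' @param n_nontargeting_cells cells carrying non-targeting control guides.
#' @param n_batches number of GEM-group-like batches.
#' @param mean_depth expected UMIs per cell.
#' @param mito_fraction_mean mean fraction of counts from mito-like genes.
#' @param seed integer seed governing all ground-truth randomness.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 400L,
                       n_programs = 3L,
                       n_regulators_per_program = 20L,
                       n_member_genes_per_program = 30L,
                       regulator_effect_scale = 1,
                       content_weight_per_program = rep(0.15, n_programs),
                       regulator_path_weight_per_program = rep(0.5, n_programs),
                       trait_noise_sd = 0.05,
                       se_range = c(0.05, 0.3),
                       shet_gamma_coupling = 0.3,
                       n_cells_per_perturbation = 166L,
                       n_nontargeting_cells = 1000L,
                       n_batches = 2L,
                       mean_depth = 11499,
                       mito_fraction_mean = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_programs = as.integer(n_programs),
    n_regulators_per_program = as.integer(n_regulators_per_program),
    n_member_genes_per_program = as.integer(n_member_genes_per_program),
    regulator_effect_scale = regulator_effect_scale,
    content_weight_per_program = as.numeric(content_weight_per_program),
    regulator_path_weight_per_program = as.numeric(regulator_path_weight_per_program),
    trait_noise_sd = trait_noise_sd, se_range = as.numeric(se_range),
    shet_gamma_coupling = shet_gamma_coupling,
    n_cells_per_perturbation = as.integer(n_cells_per_perturbation),
    n_nontargeting_cells = as.integer(n_nontargeting_cells),
    n_batches = as.integer(n_batches), mean_depth = mean_depth,
    mito_fraction_mean = mito_fraction_mean, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genes", "n_programs", "n_regulators_per_program",
              "n_member_genes_per_program", "n_cells_per_perturbation",
              "n_batches")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stopf("config field '%s' must be a positive count", nm)
  if (cfg$n_nontargeting_cells < 0L)
    stopf("n_nontargeting_cells must be non-negative")
  planted <- cfg$n_programs *
    (cfg$n_regulators_per_program + cfg$n_member_genes_per_program)
  if (planted > cfg$n_genes)
    stopf("gene budget infeasible: %d regulators+members planted but only %d genes",
          planted, cfg$n_genes)
  if (length(cfg$se_range) != 2L || any(cfg$se_range <= 0) ||
      cfg$se_range[1] >= cfg$se_range[2])
    stopf("se_range must be (low, high) with 0 < low < high")
  if (cfg$shet_gamma_coupling < 0 || cfg$shet_gamma_coupling > 1)
    stopf("shet_gamma_coupling must lie in [0, 1]")
  if (cfg$mito_fraction_mean <= 0 || cfg$mito_fraction_mean >= 1)
    stopf("mito_fraction_mean must lie in (0, 1)")
  for (nm in c("content_weight_per_program", "regulator_path_weight_per_program"))
    if (length(cfg[[nm]]) != cfg$n_programs)
      stopf("'%s' must have length n_programs", nm)
  invisible(cfg)
}

#' Simulate a planted gene-program-trait ground truth
#'
#' Plants `n_programs` programs, each with a disjoint set of regulators
#' (signed effects beta on the program's usage under knockdown) and member
#' genes (non-negative loadings). The true trait effect of gene x is
#' `gamma_x = sum_p w_p * beta_{x->p} + content_p * 1[x member of p] + eps`,
#' i.e. regulators act on the trait through the programs they control and
#' member genes through program content, mirroring the graph the downstream
#' pipeline tries to recover. Selection constraint shet is drawn from a
#' Beta(2, 5) marginal coupled to `|gamma|` through a Gaussian copula.
#'
#' @param config a [sim_config()].
#' @return an object of class `ground_truth`: list with `genes`, `loadings`
#'   (gene x program, non-negative), `regulator_effects` (gene x program,
#'   signed, zero off the planted regulator sets), `trait_weights_regulator`,
#'   `trait_weights_content`, `gamma_true`, `shet`, `program_membership`
#'   and `regulators` (named integer maps gene -> program index),
#'   `tf_assignments` (TF gene -> program), and the `config`.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_genes; K <- config$n_programs
    genes <- sprintf("g%04d", seq_len(n))
    nreg <- config$n_regulators_per_program
    nmem <- config$n_member_genes_per_program

    reg_idx <- split(seq_len(K * nreg), rep(seq_len(K), each = nreg))
    mem_idx <- split(K * nreg + seq_len(K * nmem), rep(seq_len(K), each = nmem))

    loadings <- matrix(stats::runif(n * K, 0.005, 0.015), n, K,
                       dimnames = list(genes, paste0("P", seq_len(K))))
    regeff <- matrix(0, n, K, dimnames = dimnames(loadings))
    for (p in seq_len(K)) {
      loadings[mem_idx[[p]], p] <- 1 + abs(stats::rnorm(nmem, 0, 0.1))
      mag <- config$regulator_effect_scale * stats::runif(nreg, 0.5, 1.5)
      regeff[reg_idx[[p]], p] <- sample(c(-1, 1), nreg, replace = TRUE) * mag
    }

    member_ind <- matrix(0, n, K)
    for (p in seq_len(K)) member_ind[mem_idx[[p]], p] <- 1
    gamma_true <- drop(regeff %*% config$regulator_path_weight_per_program) +
      drop(member_ind %*% config$content_weight_per_program) +
      stats::rnorm(n, 0, config$trait_noise_sd)

    # shet ~ Beta(2,5) marginal, Gaussian copula with |gamma_true|
    rho <- config$shet_gamma_coupling
    u_g <- rank(abs(gamma_true), ties.method = "average") / (n + 1)
    z <- rho * stats::qnorm(u_g) + sqrt(1 - rho^2) * stats::rnorm(n)
    shet <- stats::qbeta(stats::pnorm(z), 2, 5)

    membership <- stats::setNames(rep(seq_len(K), each = nmem),
                                  genes[unlist(mem_idx)])
    regulators <- stats::setNames(rep(seq_len(K), each = nreg),
                                  genes[unlist(reg_idx)])
    tf_assignments <- stats::setNames(seq_len(K),
                                      genes[vapply(reg_idx, `[`, 0L, 1L)])

    structure(list(
      genes = genes, loadings = loadings, regulator_effects = regeff,
      trait_weights_regulator = config$regulator_path_weight_per_program,
      trait_weights_content = config$content_weight_per_program,
      gamma_true = stats::setNames(gamma_true, genes),
      shet = stats::setNames(shet, genes),
      program_membership = membership, regulators = regulators,
      tf_assignments = tf_assignments, config = config),
      class = "ground_truth")
  })
}

#' Simulate burden-test summary statistics for one cohort
#'
#' Draws `gamma_hat = gamma_true + N(0, SE^2)` with per-gene standard errors
#' increasing in shet (constrained genes have fewer LoF carriers, hence
#' noisier burden estimates): `SE = lo + (hi - lo) * shet`. Two calls with
#' different `cohort_seed` share the same ground truth but carry independent
#' measurement noise, emulating discovery/replication cohorts.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [sim_config()].
#' @param cohort_seed seed for the cohort's measurement noise.
#' @return data.frame with columns `gene`, `gamma_hat`, `se`, `shet`.
#' @export
simulate_burden_stats <- function(truth, config = truth$config,
                                  cohort_seed = 100L) {
  se <- config$se_range[1] +
    diff(config$se_range) * truth$shet
  with_seed(cohort_seed, {
    gamma_hat <- truth$gamma_true + stats::rnorm(length(se), 0, se)
    data.frame(gene = truth$genes, gamma_hat = unname(gamma_hat),
               se = unname(se), shet = unname(truth$shet),
               stringsAsFactors = FALSE)
  })
}

# internal constants of the cell-level observation model (see vignette):
# baseline usage is Gamma(shape, rate = shape) — mean 1, CV 1/sqrt(shape) —
# so programs vary independently across cells, as real program activities do
.BASELINE_USAGE_SHAPE <- 4
.USAGE_NOISE_SD <- 0.2
.BATCH_OFFSET_SD <- 0.1
.N_MITO_GENES <- 10L
.MITO_CONCENTRATION <- 50

#' Simulate single-cell Perturb-seq-style count data
#'
#' Each cell carries exactly one perturbation label (a gene id, or
#' `"non-targeting"` for control cells). A cell's program-usage vector is
#' `max(0, baseline + batch offset + beta_{x->P} + noise)`; expected
#' expression is `loadings %*% usage` rescaled to the target depth, split
#' between the gene universe and a block of designated mito-like genes, and
#' counts are Poisson. Per-cell covariates (batch, number of expressed genes,
#' percent mito-like expression) are emitted alongside.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [sim_config()].
#' @param seed seed for the cell-level randomness (defaults to the config
#'   seed offset by 1 so truth and cells are independent draws).
#' @return an object of class `cell_data`: list with `counts` (sparse
#'   gene x cell matrix including mito-like rows), `cells` (data.frame:
#'   `cell`, `perturbation`, `batch`, `n_genes_expressed`, `pct_mito`),
#'   `genes`, `mito_genes`.
#' @export
simulate_cells <- function(truth, config = truth$config,
                           seed = config$seed + 1L) {
  validate_sim_config(config)
  if (config$n_batches < 1L) stopf("n_batches must be >= 1")
  with_seed(seed, {
    n <- config$n_genes; K <- config$n_programs
    perts <- c(rep(truth$genes, each = config$n_cells_per_perturbation),
               rep("non-targeting", config$n_nontargeting_cells))
    ncell <- length(perts)
    cells <- sprintf("c%06d", seq_len(ncell))
    batch <- paste0("batch", sample.int(config$n_batches, ncell, replace = TRUE))
    batch_off <- matrix(stats::rnorm(config$n_batches * K, 0, .BATCH_OFFSET_SD),
                        config$n_batches, K)

    pert_idx <- match(perts, truth$genes)          # NA for non-targeting
    usage <- matrix(stats::rgamma(ncell * K, shape = .BASELINE_USAGE_SHAPE,
                                  rate = .BASELINE_USAGE_SHAPE), ncell, K) +
      batch_off[as.integer(sub("batch", "", batch)), , drop = FALSE] +
      matrix(stats::rnorm(ncell * K, 0, .USAGE_NOISE_SD), ncell, K)
    shift <- matrix(0, ncell, K)
    has_t <- !is.na(pert_idx)
    shift[has_t, ] <- truth$regulator_effects[pert_idx[has_t], , drop = FALSE]
    usage <- pmax(usage + shift, 0)

    mito_genes <- sprintf("mt%02d", seq_len(.N_MITO_GENES))
    a <- config$mito_fraction_mean * .MITO_CONCENTRATION
    b <- (1 - config$mito_fraction_mean) * .MITO_CONCENTRATION
    mito_frac <- stats::rbeta(ncell, a, b)

    lam_core <- truth$loadings %*% t(usage)        # n_genes x ncell
    tot <- colSums(lam_core)
    tot[tot == 0] <- 1
    lam_core <- sweep(lam_core, 2, config$mean_depth * (1 - mito_frac) / tot, `*`)
    lam_mito <- matrix(rep(config$mean_depth * mito_frac / .N_MITO_GENES,
                           each = .N_MITO_GENES), .N_MITO_GENES, ncell)
    lam <- rbind(lam_core, lam_mito)
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncell,
                     dimnames = list(c(truth$genes, mito_genes), cells))
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

    totals <- Matrix::colSums(counts)
    pct_mito <- 100 * Matrix::colSums(counts[mito_genes, , drop = FALSE]) /
      pmax(totals, 1)
    structure(list(
      counts = counts,
      cells = data.frame(cell = cells, perturbation = perts, batch = batch,
                         n_genes_expressed = Matrix::colSums(counts > 0),
                         pct_mito = pct_mito, stringsAsFactors = FALSE),
      genes = rownames(counts), mito_genes = mito_genes),
      class = "cell_data")
  })
}

#' Simulate TF ChIP peaks around target-gene TSSs on a synthetic genome
#'
#' Genes are laid out on a single synthetic chromosome with TSSs every 10 kbp.
#' Each TF in `truth$tf_assignments` places `peaks_per_target` peaks within
#' `window_bp` of the TSS of every member gene of its assigned program, with
#' strengths (-log10 q analogues) uniform in `strength_range`; background
#' peaks are placed uniformly along the chromosome. TFs listed in
#' `background_tfs` receive only background peaks (null TFs for calibration).
#'
#' @param truth a [simulate_truth()] result with non-empty `tf_assignments`.
#' @param peaks_per_target peaks per (TF, target-gene) pair.
#' @param strength_range length-2 numeric range of peak strengths.
#' @param seed integer seed.
#' @param window_bp half-width of the placement window around target TSSs.
#' @param n_background background peaks per TF (default: as many as targeted).
#' @param background_tfs character vector of extra TF names given only
#'   background peaks.
#' @return list with `peaks` (data.frame: `tf`, `chrom`, `start`, `end`,
#'   `strength`, `summit_offset`) and `tss` (data.frame: `chrom`, `start`,
#'   `end`, `gene`, `score`, `strand`; BED, 0-based half-open).
#' @export
simulate_chip_peaks <- function(truth, peaks_per_target = 2L,
                                strength_range = c(2, 30), seed = 11L,
                                window_bp = 1000L, n_background = NULL,
                                background_tfs = character()) {
  if (length(truth$tf_assignments) == 0L) stopf("tf_assignments is empty")
  with_seed(seed, {
    n <- length(truth$genes)
    # genome order is shuffled relative to gene index so program membership
    # carries no positional signal (programs are not syntenic)
    tss_pos <- ((sample.int(n) - 1L) * 10000L + 1000L)
    genome_len <- max(tss_pos) + 10000L
    tss <- data.frame(chrom = "chrS", start = tss_pos, end = tss_pos + 1L,
                      gene = truth$genes, score = 0L, strand = "+",
                      stringsAsFactors = FALSE)

    make_peaks <- function(tf, centers, strengths) {
      centers <- pmax(centers, 100L)
      data.frame(tf = tf, chrom = "chrS", start = centers - 100L,
                 end = centers + 100L, strength = strengths,
                 summit_offset = 100L, stringsAsFactors = FALSE)
    }
    out <- list()
    for (tf in names(truth$tf_assignments)) {
      p <- truth$tf_assignments[[tf]]
      targets <- names(truth$program_membership)[truth$program_membership == p]
      tpos <- tss_pos[match(targets, truth$genes)]
      centers <- rep(tpos, each = peaks_per_target) +
        round(stats::runif(length(tpos) * peaks_per_target,
                           -window_bp, window_bp))
      nb <- if (is.null(n_background)) length(centers) else n_background
      bg <- round(stats::runif(nb, 0, genome_len))
      strengths <- stats::runif(length(centers) + nb,
                                strength_range[1], strength_range[2])
      out[[tf]] <- make_peaks(tf, c(centers, bg), strengths)
    }
    for (tf in background_tfs) {
      nb <- if (is.null(n_background)) peaks_per_target *
        sum(truth$program_membership == 1L) else n_background
      bg <- round(stats::runif(nb, 0, genome_len))
      out[[tf]] <- make_peaks(tf, bg, stats::runif(nb, strength_range[1],
                                                   strength_range[2]))
    }
    list(peaks = do.call(rbind, c(out, list(make.row.names = FALSE))),
         tss = tss)
  })
}
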