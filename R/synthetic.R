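# Synthetic scRNA-seq datasets with known ground-truth networks.
#
# A rate-based negative-binomial generative model stands in for full
# kinetic simulators at desk scale: TF programs are smooth functions of
# a latent pseudotime (bifurcating or cyclic), target rates are
# softplus-linear in their ground-truth parents, and counts add NB noise
# plus Bernoulli dropout.  Lineage-specific truths arise by tagging a
# fraction of regulator-target edges as active on one branch only, the
# aggregate a per-cell network union would produce.

#' Simulate ground-truth regulatory networks
#'
#' Builds a TF-TF backbone DAG (each non-root TF gets one earlier-TF
#' parent) plus \code{edges_per_target} TF parents per target gene;
#' housekeeping genes get no edges.  A \code{lineage_private_fraction} of
#' the TF->target edges is tagged as private to lineage CT1 or CT2
#' (alternating); each lineage truth is the shared edges plus its private
#' ones.
#'
#' @param n_tfs,n_targets,n_hk gene counts (defaults 50 / 200 / 50).
#' @param edges_per_target TF parents per target (default 2).
#' @param lineage_private_fraction fraction of TF->target edges private
#'   to one lineage (default 0.3).
#' @param rng_seed integer seed.
#' @return Object of class \code{sim_truth}: \code{edges} (data.frame
#'   regulator, target, weight, lineage in \code{c("shared","CT1","CT2")}),
#'   \code{tf_ids}, \code{target_ids}, \code{hk_ids},
#'   \code{truth_global}, \code{truth_per_lineage} ([ground_truth()]
#'   objects).
#' @export
simulate_grn <- function(n_tfs = 50, n_targets = 200, n_hk = 50,
                         edges_per_target = 2, lineage_private_fraction = 0.3,
                         rng_seed = 1) {
  stopifnot(n_tfs >= 2, n_targets >= 1, n_hk >= 0,
            edges_per_target >= 1, edges_per_target <= n_tfs,
            lineage_private_fraction >= 0, lineage_private_fraction <= 1)
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  target_ids <- sprintf("T%03d", seq_len(n_targets))
  hk_ids <- if (n_hk > 0) sprintf("HK%02d", seq_len(n_hk)) else character(0)
  with_seed(rng_seed, {
    bb <- data.frame(regulator = character(0), target = character(0))
    if (n_tfs > 1) {
      parents <- vapply(2:n_tfs, function(i) sample.int(i - 1L, 1L), integer(1))
      bb <- data.frame(regulator = tf_ids[parents], target = tf_ids[2:n_tfs])
    }
    tt <- do.call(rbind, lapply(target_ids, function(tg) {
      data.frame(regulator = sample(tf_ids, edges_per_target), target = tg)
    }))
    edges <- rbind(bb, tt)
    edges$weight <- stats::runif(nrow(edges), 0.6, 1.4) *
      sample(c(1, -1), nrow(edges), replace = TRUE, prob = c(0.8, 0.2))
    edges$lineage <- "shared"
    tt_rows <- which(edges$target %in% target_ids)
    n_priv <- round(lineage_private_fraction * length(tt_rows))
    if (n_priv > 0) {
      priv <- sample(tt_rows, n_priv)
      edges$lineage[priv] <- rep(c("CT1", "CT2"), length.out = n_priv)
    }
    all_genes <- c(tf_ids, target_ids, hk_ids)
    truth_global <- ground_truth(edges[c("regulator", "target")],
                                 regulators = tf_ids, universe = all_genes)
    truth_per_lineage <- lapply(c(CT1 = "CT1", CT2 = "CT2"), function(ct) {
      keep <- edges$lineage %in% c("shared", ct)
      ground_truth(edges[keep, c("regulator", "target")],
                   regulators = tf_ids, universe = all_genes)
    })
    structure(list(edges = edges, tf_ids = tf_ids, target_ids = target_ids,
                   hk_ids = hk_ids, truth_global = truth_global,
                   truth_per_lineage = truth_per_lineage,
                   config = list(n_tfs = n_tfs, n_targets = n_targets,
                                 n_hk = n_hk, edges_per_target = edges_per_target,
                                 lineage_private_fraction = lineage_private_fraction,
                                 rng_seed = rng_seed)),
              class = "sim_truth")
  })
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Smooth bounded TF program: Gaussian bump (bifurcating) or von
# Mises-like periodic bump (cyclic) over pseudotime s in [0, 1].
tf_program <- function(s, center, width, amp, base, cyclic) {
  if (cyclic) {
    base + amp * exp((cos(2 * pi * (s - center)) - 1) / (2 * width^2))
  } else {
    base + amp * exp(-(s - center)^2 / (2 * width^2))
  }
}

#' Simulate a single-cell expression dataset from a ground truth
#'
#' Latent pseudotime s ~ U(0, 1) per cell; for the bifurcating topology
#' each cell carries a Bernoulli(0.5) branch label and TF programs
#' diverge per branch after the bifurcation point s = 0.5; for the cyclic
#' topology programs are periodic in s.  Target rates are softplus-linear
#' in their truth parents, with lineage-private edges contributing only
#' on their branch past the bifurcation.  Counts are
#' NB(rate x library factor, 1/nb_dispersion) with optional Bernoulli
#' dropout.  Fate rows interpolate from (0.5, 0.5) at the root toward
#' the branch indicator (1,0)/(0,1) at the terminal end of the
#' trajectory, as a Markov fate-mapping tool would report.
#'
#' @param truth a \code{sim_truth}.
#' @param topology \code{"bifurcating"} or \code{"cyclic"}.
#' @param n_cells number of cells (default 4000).
#' @param nb_dispersion NB dispersion (variance = mu + disp * mu^2;
#'   0 = Poisson; default 0.5).
#' @param dropout extra Bernoulli dropout probability (default 0; droplet
#'   UMI counts are negative-binomial without extra zero inflation, the
#'   knob exists for sensitivity analyses).
#' @param mean_library expected total counts per cell across the modeled
#'   gene panel (default 150: the share of a few-thousand-UMI droplet
#'   library that falls on a 300-gene panel).
#' @param gene_scale_sdlog sd(log) of the per-gene expression-scale
#'   factors (default 1.2): real scRNA-seq gene abundances span orders
#'   of magnitude, so most genes are low-count while a few dominate the
#'   library.
#' @param regulatory_lag kinetic delay, in pseudotime units, between a
#'   regulator's state and its targets' transcriptional response
#'   (default 0.2); gives regulation the temporal precedence that
#'   kinetic simulators produce through synthesis/maturation delays.
#' @param intrinsic_noise sd(log) of cell-intrinsic (transcriptional
#'   bursting) rate fluctuations (default 0.8): each cell's realized
#'   rate deviates log-normally from the manifold rate, so single-cell
#'   profiles are noisy realizations of the cell state rather than
#'   deterministic functions of it.
#' @param rng_seed integer seed.
#' @return Object of class \code{sim_dataset}: \code{counts}
#'   ([count_matrix()]), \code{truth_global}, \code{truth_per_lineage},
#'   \code{fates} ([fate_matrix()] or NULL for cyclic),
#'   \code{lineage_of_cell} (\code{root}/\code{CT1}/\code{CT2} or
#'   \code{cycle}), \code{pseudotime}, \code{topology}, \code{config}.
#' @export
simulate_expression <- function(truth, topology = c("bifurcating", "cyclic"),
                                n_cells = 4000, nb_dispersion = 0.5,
                                dropout = 0, mean_library = 150,
                                gene_scale_sdlog = 1.2, regulatory_lag = 0.2,
                                intrinsic_noise = 0.8, rng_seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  topology <- match.arg(topology)
  if (nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (dropout < 0 || dropout > 1) stopf("dropout must lie in [0, 1]")
  cyclic <- topology == "cyclic"
  tf_ids <- truth$tf_ids
  n_tfs <- length(tf_ids)
  with_seed(rng_seed, {
    s <- stats::runif(n_cells)
    branch <- if (cyclic) rep(1L, n_cells) else sample(1:2, n_cells, replace = TRUE)
    past <- !cyclic & s > 0.5

    # TF rates: root TFs are bump programs; every TF additionally gets a
    # branch-specific amplitude modifier past the bifurcation so the two
    # lineages diverge transcriptionally.
    centers <- stats::runif(n_tfs)
    widths <- stats::runif(n_tfs, 0.12, 0.35)
    amps <- stats::runif(n_tfs, 1.5, 4)
    bases <- stats::runif(n_tfs, 0.1, 0.5)
    branch_mod <- matrix(stats::runif(n_tfs * 2, 0.2, 1.8), n_tfs, 2)
    bb <- truth$edges[truth$edges$target %in% tf_ids, , drop = FALSE]
    # TF rate matrix evaluated at an arbitrary pseudotime vector; the
    # branch label stays the cell's own, the past-bifurcation flag is
    # taken at the evaluation time.
    tf_rates_at <- function(s_eval) {
      past_e <- !cyclic & s_eval > 0.5
      tfr <- matrix(0, n_tfs, n_cells, dimnames = list(tf_ids, NULL))
      for (i in seq_len(n_tfs)) {
        r <- tf_program(s_eval, centers[i], widths[i], amps[i], bases[i], cyclic)
        if (!cyclic) r <- r * ifelse(past_e, branch_mod[i, branch], 1)
        tfr[i, ] <- r
      }
      # backbone edges: child TF blends in its parent's signal so TF-TF
      # edges carry covariation too
      for (e in seq_len(nrow(bb))) {
        child <- bb$target[e]; parent <- bb$regulator[e]
        tfr[child, ] <- 0.5 * tfr[child, ] +
          0.5 * softplus(bb$weight[e] * tfr[parent, ])
      }
      tfr
    }
    tf_rate <- tf_rates_at(s)
    # targets respond to their regulators' state one kinetic delay ago
    # (transcription/maturation lag), giving regulation a temporal arrow
    s_lag <- if (cyclic) (s - regulatory_lag) %% 1 else pmax(s - regulatory_lag, 0)
    tf_rate_lag <- if (regulatory_lag > 0) tf_rates_at(s_lag) else tf_rate

    # Target rates: softplus of the weighted parent sum of lagged TF
    # states; lineage-private edges contribute only on their branch past
    # the bifurcation.
    tt <- truth$edges[truth$edges$target %in% truth$target_ids, , drop = FALSE]
    tgt_rate <- matrix(0, length(truth$target_ids), n_cells,
                       dimnames = list(truth$target_ids, NULL))
    lin_label <- c("CT1", "CT2")
    for (tg in truth$target_ids) {
      ee <- tt[tt$target == tg, , drop = FALSE]
      acc <- matrix(0, nrow(ee), n_cells)
      for (e in seq_len(nrow(ee))) {
        contrib <- ee$weight[e] * tf_rate_lag[ee$regulator[e], ]
        if (ee$lineage[e] != "shared") {
          on_branch <- past & (lin_label[branch] == ee$lineage[e])
          contrib <- contrib * on_branch
        }
        acc[e, ] <- contrib
      }
      tgt_rate[tg, ] <- softplus(colSums(acc))
    }
    hk_rate <- matrix(stats::runif(length(truth$hk_ids), 0.5, 3),
                      length(truth$hk_ids), n_cells,
                      dimnames = list(truth$hk_ids, NULL))

    rate <- rbind(tf_rate, tgt_rate, hk_rate)
    if (gene_scale_sdlog > 0) {
      rate <- rate * stats::rlnorm(nrow(rate), 0, gene_scale_sdlog)
    }
    if (intrinsic_noise > 0) {
      # cell-intrinsic (burst-like) rate fluctuations: each cell's
      # realized rate deviates log-normally from its manifold rate, the
      # biological noise component that neighbourhood aggregation
      # averages out but more cells alone cannot
      rate <- rate * matrix(stats::rlnorm(length(rate), 0, intrinsic_noise),
                            nrow(rate))
    }
    lib <- stats::rlnorm(n_cells, 0, 0.25)
    mu <- sweep(rate, 2, lib * mean_library / max(1e-9, sum(rowMeans(rate))), "*")
    n_entries <- length(mu)
    counts <- if (nb_dispersion == 0) {
      stats::rpois(n_entries, lambda = as.vector(mu))
    } else {
      stats::rnbinom(n_entries, mu = as.vector(mu), size = 1 / nb_dispersion)
    }
    if (dropout > 0) {
      counts <- counts * (stats::runif(n_entries) >= dropout)
    }
    counts <- matrix(counts, nrow(rate), n_cells,
                     dimnames = list(rownames(rate),
                                     sprintf("cell%04d", seq_len(n_cells))))

    fates <- NULL
    lineage_of_cell <- rep("cycle", n_cells)
    if (!cyclic) {
      # graded fate probability: (0.5, 0.5) at the root, approaching the
      # branch indicator (1,0)/(0,1) toward the terminal end, as a
      # Markov fate-mapping tool would report
      p1 <- ifelse(branch == 1L, 0.5 + 0.5 * s, 0.5 - 0.5 * s)
      fates <- fate_matrix(cbind(CT1 = p1, CT2 = 1 - p1))
      lineage_of_cell <- ifelse(past, lin_label[branch], "root")
    }
    structure(list(
      counts = count_matrix(counts),
      truth_global = truth$truth_global,
      truth_per_lineage = truth$truth_per_lineage,
      truth = truth,
      fates = fates,
      lineage_of_cell = lineage_of_cell,
      pseudotime = s, branch = branch, topology = topology,
      config = c(truth$config,
                 list(topology = topology, n_cells = n_cells,
                      nb_dispersion = nb_dispersion, dropout = dropout,
                      mean_library = mean_library,
                      gene_scale_sdlog = gene_scale_sdlog,
                      regulatory_lag = regulatory_lag,
                      intrinsic_noise = intrinsic_noise,
                      expr_rng_seed = rng_seed))),
      class = "sim_dataset")
  })
}

#' One-call simulated dataset with the default study configuration
#'
#' @inheritParams simulate_grn
#' @inheritParams simulate_expression
#' @return A \code{sim_dataset}.
#' @export
simulate_dataset <- function(topology = c("bifurcating", "cyclic"),
                             n_cells = 4000, n_tfs = 50, n_targets = 200,
                             n_hk = 50, edges_per_target = 2,
                             lineage_private_fraction = 0.3,
                             nb_dispersion = 0.5, dropout = 0,
                             gene_scale_sdlog = 1.2, regulatory_lag = 0.2,
                             intrinsic_noise = 0.8, rng_seed = 1) {
  truth <- simulate_grn(n_tfs, n_targets, n_hk, edges_per_target,
                        lineage_private_fraction, rng_seed = child_seed(rng_seed, 1))
  simulate_expression(truth, topology, n_cells = n_cells,
                      nb_dispersion = nb_dispersion, dropout = dropout,
                      gene_scale_sdlog = gene_scale_sdlog,
                      regulatory_lag = regulatory_lag,
                      intrinsic_noise = intrinsic_noise,
                      rng_seed = child_seed(rng_seed, 2))
}

#' Write a simulated dataset as a plain-text fixture directory
#'
#' Layout: \code{counts.mtx} + \code{genes.tsv}/\code{barcodes.tsv},
#' \code{truth_global.tsv}, \code{truth_CT1.tsv}/\code{truth_CT2.tsv}
#' (bifurcating), \code{fates.csv}, \code{labels.tsv},
#' \code{config.json}.
#'
#' @param dataset a \code{sim_dataset}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(dataset$counts, file.path(dir, "counts.mtx"), format = "mtx")
  utils::write.table(dataset$truth_global$edges, file.path(dir, "truth_global.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth_per_lineage)) {
    for (ct in names(dataset$truth_per_lineage)) {
      utils::write.table(dataset$truth_per_lineage[[ct]]$edges,
                         file.path(dir, sprintf("truth_%s.tsv", ct)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(dataset$fates)) {
    utils::write.csv(as.data.frame(unclass(dataset$fates)),
                     file.path(dir, "fates.csv"), row.names = FALSE)
  }
  utils::write.table(
    data.frame(cell = dataset$counts$cell_ids,
               lineage = dataset$lineage_of_cell,
               pseudotime = dataset$pseudotime),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return List with \code{counts}, \code{truth_global},
#'   \code{truth_per_lineage}, \code{fates}, \code{labels},
#'   \code{config}.
#' @export
load_fixture <- function(dir) {
  counts <- load_counts(file.path(dir, "counts.mtx"), format = "mtx")
  config <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  tf_ids <- grep("^TF", counts$gene_ids, value = TRUE)
  read_truth <- function(p) {
    df <- utils::read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    ground_truth(df[c("regulator", "target")], regulators = tf_ids,
                 universe = counts$gene_ids)
  }
  truth_global <- read_truth(file.path(dir, "truth_global.tsv"))
  lin_files <- list.files(dir, pattern = "^truth_CT", full.names = TRUE)
  truth_per_lineage <- if (length(lin_files)) {
    stats::setNames(lapply(lin_files, read_truth),
                    sub("^truth_(CT\\d+)\\.tsv$", "\\1", basename(lin_files)))
  } else NULL
  fates <- if (file.exists(file.path(dir, "fates.csv"))) {
    read_fates(file.path(dir, "fates.csv"))
  } else NULL
  labels <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  list(counts = counts, truth_global = truth_global,
       truth_per_lineage = truth_per_lineage, fates = fates,
       labels = labels, config = config)
}
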