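#' Configuration for an end-to-end rooting experiment
#'
#' Bundles the dataset source, the rate policies to compare, and the AU
#' settings for [run_experiment()].
#'
#' @param sim A [sim_config()] describing a simulated dataset, or `NULL`
#'   when `species_tree_file` / `gene_trees_file` are given.
#' @param species_tree_file,gene_trees_file Optional newick inputs (a
#'   rooted or unrooted species tree; one gene tree per line).
#' @param missing_fractions_file Optional TSV of per-species missing
#'   fractions.
#' @param policies List of [rate_policy()] objects to compare (at least
#'   one).
#' @param alpha AU rejection threshold.
#' @param B,scales AU bootstrap settings.
#' @param block_size Families per block in the power analysis.
#' @param power_keys Rate keys for the power analysis (set `character(0)`
#'   to skip it).
#' @param controls Run the single-copy / random-subset controls?
#' @param seed Master seed (mandatory; drives the AU resampling and, for
#'   simulated sources, the data).
#' @param out Output directory, or `NULL` to skip writing files.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = NULL, species_tree_file = NULL,
                              gene_trees_file = NULL,
                              missing_fractions_file = NULL,
                              policies = list(rate_policy("free")),
                              alpha = 0.05, B = 10000L,
                              scales = seq(0.5, 1.4, by = 0.1),
                              block_size = 100L,
                              power_keys = c("duplication", "transfer", "loss"),
                              controls = TRUE, seed, out = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(sim) && (is.null(species_tree_file) || is.null(gene_trees_file)))
    stop("either a sim_config or species/gene tree files are required")
  if (!length(policies)) stop("at least one rate policy is required")
  if (!all(vapply(policies, inherits, logical(1), "rate_policy")))
    stop("policies must be rate_policy objects")
  structure(list(sim = sim, species_tree_file = species_tree_file,
                 gene_trees_file = gene_trees_file,
                 missing_fractions_file = missing_fractions_file,
                 policies = policies, alpha = alpha, B = as.integer(B),
                 scales = scales, block_size = as.integer(block_size),
                 power_keys = power_keys, controls = controls,
                 seed = as.integer(seed), out = out),
            class = "experiment_config")
}

#' Run a full rooting experiment
#'
#' Reproduces the study design on one dataset: (E1) root sets under each
#' rate policy — the free 1:1-seeded analysis plus any constrained T:D
#' policies, whose per-family transfer rates are taken from the free fits
#' at the free scan's maximum-likelihood root; (E2) single-copy
#' species-complete subset and a size-matched random subset, AU-tested on
#' the free log-likelihood matrix; (E3) power curves per rate key. All
#' stages are deterministic given the config seed.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print stage progress.
#' @return An object of class `experiment_report`: `dataset` (for
#'   simulated sources), `true_branch` (when known), `scans`, `au`,
#'   `root_sets`, `comparison` (policy table), `rate_summaries`,
#'   `controls`, `power`, `free_td_quantiles`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(...)

  # --- dataset ------------------------------------------------------------
  dataset <- NULL; true_branch <- NA_integer_
  if (!is.null(cfg$sim)) {
    say("simulating dataset (", cfg$sim$preset, ", ",
        cfg$sim$n_families, " families)")
    dataset <- simulate_dataset(cfg$sim)
    families <- dataset$families
    ut <- unrooted_species_tree(ape::unroot(dataset$species_phy),
                                missing = .expand_missing(cfg$sim, dataset))
    true_branch <- true_root_branch(ut, dataset$species_phy)
  } else {
    miss <- if (!is.null(cfg$missing_fractions_file))
      read_missing_fractions(cfg$missing_fractions_file) else NULL
    sp <- parse_newick(paste(readLines(cfg$species_tree_file), collapse = ""))
    rooted_in <- ape::is.rooted(sp) && length(sp$tip.label) >= 3L
    ut <- unrooted_species_tree(sp, missing = miss)
    if (rooted_in)
      true_branch <- tryCatch(true_root_branch(ut, sp),
                              error = function(e) NA_integer_)
    families <- read_gene_trees(cfg$gene_trees_file,
                                species = ut$phy$tip.label)
  }

  # --- E1: root sets per policy -------------------------------------------
  say("free-policy root scan (", length(families), " families)")
  free_scan <- root_scan(families, ut, rate_policy("free"))
  # reference fits for constrained policies: free mode at the free scan's
  # maximum-likelihood root
  need_base <- any(vapply(cfg$policies, function(p) p$kind != "free",
                          logical(1)))
  base_fits <- NULL
  if (need_base) {
    say("free fits taken at argmax root ", free_scan$argmax)
    k <- match(free_scan$argmax, free_scan$branches)
    base_fits <- lapply(seq_along(families), function(i) {
      rates <- c(delta = free_scan$delta[k, i], tau = free_scan$tau[k, i],
                 lambda = free_scan$lambda[k, i])
      structure(list(id = families[[i]]$id, mode = "free", rates = rates,
                     loglik = free_scan$ll[k, i], td = td_ratio(rates),
                     converged = TRUE, evals = NA_integer_),
                class = "family_fit")
    })
  }
  scans <- list(); au <- list(); sets <- list(); summaries <- list()
  for (p in cfg$policies) {
    tag <- policy_label(p)
    say("policy ", tag)
    sc <- if (p$kind == "free") free_scan
          else root_scan(families, ut, p, base_fits = base_fits)
    a <- au_test(sc, B = cfg$B, scales = cfg$scales, seed = cfg$seed)
    rs <- root_set(a, cfg$alpha)
    scans[[tag]] <- sc; au[[tag]] <- a; sets[[tag]] <- rs
    # flux summary at the policy's argmax root
    k <- match(sc$argmax, sc$branches)
    summaries[[tag]] <- summarize_rates(data.frame(
      family_id = colnames(sc$ll), delta = sc$delta[k, ],
      tau = sc$tau[k, ], lambda = sc$lambda[k, ]))
  }
  comparison <- data.frame(
    policy = names(sets),
    n_retained = vapply(sets, function(s) length(s$retained), integer(1)),
    argmax = vapply(scans, function(s) as.character(s$argmax), character(1)),
    contains_true = if (is.na(true_branch)) NA else
      vapply(sets, function(s) as.character(true_branch) %in% s$retained,
             logical(1)),
    retained = vapply(sets, function(s)
      paste(sort(as.integer(s$retained)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)

  # per-family fitted T:D quantiles under the free policy (sanity surface
  # for abnormal ratio ranges)
  td <- vapply(free_scan$ref_fits, function(f) as.numeric(f$td), numeric(1))
  td_q <- quantile(td[is.finite(td)],
                   probs = c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1), na.rm = TRUE)

  # --- E2: single-copy and size-matched random subset controls ------------
  controls <- NULL
  if (cfg$controls && !is.null(dataset) &&
      length(dataset$singlecopy_ids) >= 2L) {
    say("controls: single-copy subset (", length(dataset$singlecopy_ids),
        " families) + random subset")
    ids <- colnames(free_scan$ll)
    sc_ids <- intersect(ids, dataset$singlecopy_ids)
    a_sc <- au_test(free_scan$ll[, sc_ids, drop = FALSE], B = cfg$B,
                    scales = cfg$scales, seed = cfg$seed + 1L)
    set_sc <- root_set(a_sc, cfg$alpha)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(cfg$seed + 2L)
    rnd_ids <- sample(ids, length(sc_ids))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    a_rnd <- au_test(free_scan$ll[, rnd_ids, drop = FALSE], B = cfg$B,
                     scales = cfg$scales, seed = cfg$seed + 3L)
    set_rnd <- root_set(a_rnd, cfg$alpha)
    controls <- list(singlecopy_ids = sc_ids, random_ids = rnd_ids,
                     singlecopy_set = set_sc, random_set = set_rnd)
  }

  # --- E3: power curves ----------------------------------------------------
  power <- list()
  if (length(cfg$power_keys) &&
      length(families) >= 2L * cfg$block_size) {
    for (key in cfg$power_keys) {
      say("power analysis: ", key)
      power[[key]] <- power_analysis(free_scan, key = key,
                                     block_size = cfg$block_size,
                                     alpha = cfg$alpha, B = cfg$B,
                                     scales = cfg$scales,
                                     seed = cfg$seed + 10L)
    }
  }

  report <- structure(list(dataset = dataset, true_branch = true_branch,
                           scans = scans, au = au, root_sets = sets,
                           comparison = comparison,
                           rate_summaries = summaries,
                           free_td_quantiles = td_q,
                           controls = controls, power = power,
                           config = cfg),
                      class = "experiment_report")
  if (!is.null(cfg$out)) write_experiment(report, cfg$out)
  report
}

.expand_missing <- function(simcfg, dataset) {
  miss <- simcfg$missing
  if (is.null(miss)) return(NULL)
  tips <- dataset$species_phy$tip.label
  if (is.null(names(miss)) && length(miss) == 1L)
    return(setNames(rep(miss, length(tips)), tips))
  miss
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", nrow(x$comparison), "policies",
      if (!is.na(x$true_branch)) paste0("(true root branch ", x$true_branch, ")"),
      "\n")
  print(x$comparison[, c("policy", "n_retained", "argmax", "contains_true")],
        row.names = FALSE)
  invisible(x)
}

#' Write an experiment report to a directory of TSV/newick files
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_experiment <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$dataset)) write_sim_dataset(report$dataset, dir)
  write.table(report$comparison, file.path(dir, "rootset_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_rate_summary_tsv(report$rate_summaries,
                         file.path(dir, "rate_summaries.tsv"))
  for (tag in names(report$scans)) {
    write_scan_tsv(report$scans[[tag]], report$au[[tag]],
                   report$root_sets[[tag]], dir, tag = tag)
    write.table(fits_table_from_scan(report$scans[[tag]]),
                file.path(dir, paste0(tag, "_fits.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  qt <- report$free_td_quantiles
  write.table(data.frame(quantile = names(qt), td_ratio = as.numeric(qt)),
              file.path(dir, "free_td_quantiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(report$power))
    write_power_tsv(report$power[[key]],
                    file.path(dir, paste0("power_", key, ".tsv")))
  invisible(dir)
}

#' Per-family fit table at a scan's maximum-likelihood root
#'
#' @param scan A `root_scan`.
#' @return data.frame mirroring [fits_table()].
#' @export
fits_table_from_scan <- function(scan) {
  k <- match(scan$argmax, scan$branches)
  delta <- scan$delta[k, ]; tau <- scan$tau[k, ]
  data.frame(family_id = colnames(scan$ll),
             mode = policy_label(scan$policy),
             delta = delta, tau = tau, lambda = scan$lambda[k, ],
             loglik = scan$ll[k, ],
             td_ratio = ifelse(delta > 0, tau / delta, NA_real_),
             converged = TRUE, stringsAsFactors = FALSE)
}
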