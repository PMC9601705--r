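#' Run a self-contained synthetic segmentation experiment
#'
#' Generates a seeded synthetic dataset, trains a network on the first
#' `n_train` arches, and evaluates overall accuracy and mean IoU on the
#' remaining `n_test` held-out arches. Every parameter, flag and seed is
#' recorded in the returned manifest.
#'
#' @param n_train,n_test number of training / held-out arches.
#' @param target_faces faces per arch.
#' @param epochs training epochs.
#' @param batch_size meshes per optimizer step.
#' @param network a [network_config()]; its `seed` is re-derived from `seed`.
#' @param base_params an [arch_params()] template for the generator.
#' @param seed master seed for data generation and training.
#' @param verbose print per-epoch progress.
#' @return list with `fit` (from [train_network()]), `test` (per-model and
#'   mean OA/mIoU), and `manifest`.
#' @export
run_experiment <- function(n_train = 8L, n_test = 2L, target_faces = 2000L,
                           epochs = 30L, batch_size = 1L,
                           network = network_config(), base_params = NULL,
                           seed = 1L, verbose = FALSE) {
  if (is.null(base_params)) base_params <- arch_params()
  base_params$target_faces <- as.integer(target_faces)
  ds <- make_dataset(n_train + n_test, base_params, seed = seed)
  train_meshes <- ds$meshes[seq_len(n_train)]
  test_meshes <- ds$meshes[n_train + seq_len(n_test)]
  network$seed <- as.integer((seed * 7919L + 13L) %% .Machine$integer.max)
  tcfg <- train_config(network = network, epochs = epochs,
                       batch_size = batch_size,
                       seed = as.integer((seed * 104729L + 7L) %%
                                           .Machine$integer.max))
  fit <- train_network(train_meshes, tcfg, verbose = verbose)
  per_model <- t(vapply(test_meshes, function(m) {
    res <- forward_network(fit$net, m)
    c(oa = overall_accuracy(res$labels, m$face_labels),
      miou = mean_iou(res$labels, m$face_labels, network$C))
  }, numeric(2)))
  test <- list(oa = mean(per_model[, "oa"]), miou = mean(per_model[, "miou"]),
               per_model = per_model)
  manifest <- list(seed = as.integer(seed), n_train = n_train,
                   n_test = n_test, target_faces = as.integer(target_faces),
                   epochs = as.integer(epochs),
                   batch_size = as.integer(batch_size),
                   network = unclass(network),
                   generator = ds$manifest)
  list(fit = fit, test = test, manifest = manifest)
}

#' Ablation harness
#'
#' Runs the standard ablation deformations of the network end-to-end on the
#' synthetic experiment: `only_pk` / `only_nk` (single geometric encoding),
#' `branch_S` / `branch_L` (single receptive-field branch), `no_eca`
#' (channel attention removed), and `vary_n` (a sweep over input face
#' counts). Each run's manifest logs the deformation and the resulting
#' config flags; no accuracy ordering is asserted anywhere — rankings are
#' dataset-dependent.
#'
#' @param deformations character vector of deformation names (default all).
#' @param n_values face counts for the `vary_n` sweep.
#' @param ... arguments passed on to [run_experiment()] (`n_train`,
#'   `epochs`, `target_faces`, `seed`, ...).
#' @param network base [network_config()] the deformations modify.
#' @return named list of [run_experiment()] results, one per run.
#' @export
run_ablation <- function(deformations = c("only_pk", "only_nk", "branch_S",
                                          "branch_L", "no_eca", "vary_n"),
                         n_values = c(600L, 1000L, 2000L),
                         network = network_config(), ...) {
  deformations <- match.arg(deformations, several.ok = TRUE)
  apply_deformation <- function(cfg, d) {
    switch(d,
      only_pk = { cfg$use_nk <- FALSE; cfg },
      only_nk = { cfg$use_pk <- FALSE; cfg },
      branch_S = { cfg$use_branch_L <- FALSE; cfg },
      branch_L = { cfg$use_branch_S <- FALSE; cfg },
      no_eca = { cfg$use_eca <- FALSE; cfg })
  }
  dots <- list(...)
  out <- list()
  for (d in deformations) {
    if (d == "vary_n") {
      for (nv in n_values) {
        key <- sprintf("vary_n_%d", nv)
        args <- dots
        args$target_faces <- nv
        args$network <- network
        res <- do.call(run_experiment, args)
        res$manifest$deformation <- key
        out[[key]] <- res
      }
    } else {
      res <- do.call(run_experiment,
                     c(list(network = apply_deformation(network, d)), dots))
      res$manifest$deformation <- d
      out[[d]] <- res
    }
  }
  out
}
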