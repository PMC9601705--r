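#' Training configuration
#'
#' @param network a [network_config()] (embedded into every artifact).
#' @param epochs training epochs (default 200).
#' @param batch_size meshes per optimizer step (default 4); gradients are
#'   averaged over the batch.
#' @param lr initial Adam learning rate (default 0.001).
#' @param plateau_factor multiplicative learning-rate decay applied when the
#'   monitored loss stops improving (default 0.5).
#' @param patience epochs without improvement before decaying (default 10).
#' @param min_lr floor for the decayed learning rate (default 1e-5).
#' @param seed integer seed governing shuffling, cropping and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(network = network_config(), epochs = 200L,
                         batch_size = 4L, lr = 0.001,
                         plateau_factor = 0.5, patience = 10L,
                         min_lr = 1e-5, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, plateau_factor > 0,
            plateau_factor <= 1, patience >= 1, min_lr > 0)
  structure(list(network = network, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 plateau_factor = plateau_factor,
                 patience = as.integer(patience), min_lr = min_lr,
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_step <- function(ps, lr, grad_scale = 1, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  ps$step <- ps$step + 1L
  t <- ps$step
  for (nm in ps$order) {
    p <- ps$params[[nm]]
    if (is.null(p$grad)) next
    gr <- p$grad * grad_scale
    p$m <- beta1 * p$m + (1 - beta1) * gr
    p$v <- beta2 * p$v + (1 - beta2) * gr^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(ps)
}

zero_grads <- function(ps) {
  for (nm in ps$order) ps$params[[nm]]$grad <- NULL
  invisible(ps)
}

# precompute features and neighbourhoods once per mesh
prep_training_item <- function(mesh, cfg) {
  feats <- if (inherits(mesh, "face_features")) mesh
           else assemble_features(mesh, center = cfg$center)
  if (is.null(feats$labels)) stop("training meshes must carry face labels")
  list(feats = feats,
       nbrS = if (cfg$use_branch_S) knn_indices(feats$centroids, cfg$K_small),
       nbrL = if (cfg$use_branch_L) knn_indices(feats$centroids, cfg$K_large),
       labels = feats$labels)
}

# label-preserving random face crop to n faces (uniform subset)
crop_mesh_faces <- function(mesh, n) {
  keep <- sort(sample.int(n_faces(mesh), n))
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[f], ncol = 3),
                face_labels = mesh$face_labels[keep],
                n_classes = mesh$n_classes, provenance = mesh$provenance)
}

#' Train a segmentation network
#'
#' Optimizes the generalized Dice loss with Adam, decaying the learning rate
#' on plateau of the monitored loss (validation if `val_meshes` is given,
#' else training). Meshes in a batch must share a face count; when they do
#' not, every mesh is randomly cropped once, label-preservingly, to the
#' smallest face count in the dataset. Fully reproducible given
#' `config$seed`.
#'
#' @param meshes list of labeled [triangle_mesh()] (or `face_features`).
#' @param config a [train_config()].
#' @param val_meshes optional list of labeled meshes for validation metrics
#'   and plateau monitoring.
#' @param verbose print one line per epoch.
#' @param log_csv optional path for the per-epoch metrics log.
#' @return list with `net` (the trained `dental_network`, best-validation
#'   weights when a validation set is given), `history` (per-epoch
#'   data.frame), `best_epoch` and `config`.
#' @export
train_network <- function(meshes, config = train_config(), val_meshes = NULL,
                          verbose = FALSE, log_csv = NULL) {
  if (length(meshes) < 1L) stop("empty training dataset")
  ncfg <- config$network
  for (m in meshes) {
    nc <- if (inherits(m, "face_features")) m$n_classes else m$n_classes
    if (!is.null(nc) && nc > ncfg$C)
      stop(sprintf("mesh has %d classes but the network emits C = %d",
                   nc, ncfg$C))
  }
  net <- init_network(ncfg)
  history <- NULL
  best <- list(loss = Inf, epoch = 0L, values = NULL)
  with_seed(config$seed, {
    if (config$batch_size > 1L) {
      counts <- vapply(meshes, n_faces, integer(1))
      if (length(unique(counts)) > 1L) {
        nmin <- min(counts)
        meshes <- lapply(meshes, function(m)
          if (n_faces(m) > nmin) crop_mesh_faces(m, nmin) else m)
      }
    }
    items <- lapply(meshes, prep_training_item, cfg = ncfg)
    val_items <- if (!is.null(val_meshes))
      lapply(val_meshes, prep_training_item, cfg = ncfg)
    lr <- config$lr
    since_best <- 0L
    monitor_best <- Inf
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(items))
      losses <- numeric(0)
      bstart <- seq.int(1L, length(ord), by = config$batch_size)
      for (bs in bstart) {
        batch <- ord[bs:min(bs + config$batch_size - 1L, length(ord))]
        zero_grads(net$ps)
        for (ix in batch) {
          it <- items[[ix]]
          out <- nf_forward(net, it$feats, training = TRUE,
                            nbr_small = it$nbrS, nbr_large = it$nbrL)
          loss <- ad_gdl(out$g, out$probs, it$labels)
          ad_backward(out$g, loss, scale = 1 / length(batch))
          losses <- c(losses, loss$value[1])
        }
        adam_step(net$ps, lr)
      }
      train_loss <- mean(losses)
      val_row <- list(val_loss = NA_real_, val_oa = NA_real_,
                      val_miou = NA_real_)
      if (!is.null(val_meshes)) {
        vl <- vapply(val_items, function(it) {
          out <- nf_forward(net, it$feats, training = FALSE,
                            nbr_small = it$nbrS, nbr_large = it$nbrL)
          pred <- max.col(out$probs$value, ties.method = "first") - 1L
          c(generalized_dice_loss(out$probs$value, it$labels),
            overall_accuracy(pred, it$labels),
            mean_iou(pred, it$labels, ncfg$C))
        }, numeric(3))
        val_row <- list(val_loss = mean(vl[1, ]), val_oa = mean(vl[2, ]),
                        val_miou = mean(vl[3, ]))
      }
      monitor <- if (!is.null(val_meshes)) val_row$val_loss else train_loss
      if (monitor < best$loss) {
        best <- list(loss = monitor, epoch = epoch,
                     values = snapshot_params(net$ps))
      }
      if (monitor < monitor_best - 1e-7) {
        monitor_best <- monitor
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) {
          lr <- max(config$min_lr, lr * config$plateau_factor)
          since_best <- 0L
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = train_loss,
        val_loss = val_row$val_loss, val_oa = val_row$val_oa,
        val_miou = val_row$val_miou))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val_oa %s", epoch, train_loss,
                        ifelse(is.na(val_row$val_oa), "-",
                               sprintf("%.3f", val_row$val_oa))))
    }
    if (!is.null(val_meshes) && !is.null(best$values))
      restore_params(net$ps, best$values)
  })
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  list(net = net, history = history, best_epoch = best$epoch,
       config = config)
}

snapshot_params <- function(ps) {
  vals <- lapply(ps$order, function(nm) ps$params[[nm]]$value)
  names(vals) <- ps$order
  states <- lapply(ls(ps$states), function(nm)
    list(mean = ps$states[[nm]]$mean, var = ps$states[[nm]]$var))
  names(states) <- ls(ps$states)
  list(params = vals, states = states, step = ps$step)
}

restore_params <- function(ps, snap) {
  for (nm in names(snap$params)) ps$params[[nm]]$value <- snap$params[[nm]]
  for (nm in names(snap$states)) {
    ps$states[[nm]]$mean <- snap$states[[nm]]$mean
    ps$states[[nm]]$var <- snap$states[[nm]]$var
  }
  ps$step <- snap$step
  invisible(ps)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single archive holding every weight, the batch-norm
#' running statistics, the full [network_config()] and a format version, so
#' a prediction run needs nothing else.
#'
#' @param net a `dental_network` (or the result of [train_network()]).
#' @param path checkpoint file path.
#' @return `path` (save) or a `dental_network` (load).
#' @export
save_checkpoint <- function(net, path) {
  if (!inherits(net, "dental_network") && !is.null(net$net)) net <- net$net
  stopifnot(inherits(net, "dental_network"))
  obj <- list(format = "dentalseg-checkpoint", version = 1L,
              config = net$config, snapshot = snapshot_params(net$ps),
              order = net$ps$order)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable checkpoint: ", path))
  if (!identical(obj$format, "dentalseg-checkpoint"))
    stop("not a dentalseg checkpoint (missing format tag): ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported checkpoint version: ", obj$version)
  net <- init_network(obj$config)
  restore_params(net$ps, obj$snapshot)
  net
}

#' Predict labels for a mesh
#'
#' @param net a `dental_network` or a checkpoint path.
#' @param mesh a [triangle_mesh()] or a mesh file path.
#' @param labels_out optional path for the predicted label sidecar.
#' @return list with `mesh` (labels attached), `result`
#'   (a `segmentation_result`) and the evaluation-ready label vector.
#' @export
predict_mesh <- function(net, mesh, labels_out = NULL) {
  if (is.character(net)) net <- load_checkpoint(net)
  if (is.character(mesh)) mesh <- read_mesh(mesh)
  res <- forward_network(net, mesh)
  mesh$face_labels <- res$labels
  mesh$n_classes <- net$config$C
  if (!is.null(labels_out))
    write_labels(res$labels, labels_out, n_classes = net$config$C)
  list(mesh = mesh, result = res, labels = res$labels)
}

#' Evaluate predicted labels against ground truth
#'
#' @param pred_path,truth_path label sidecar files (see [read_labels()]).
#' @param path optional JSON report output path.
#' @return an [evaluation_report()].
#' @export
evaluate_labels <- function(pred_path, truth_path, path = NULL) {
  pred <- read_labels(pred_path)
  truth <- read_labels(truth_path)
  if (length(pred) != length(truth))
    stop(sprintf("prediction (%d) and truth (%d) differ in length",
                 length(pred), length(truth)))
  n_classes <- max(attr(pred, "n_classes"), attr(truth, "n_classes"))
  evaluation_report(pred, truth, n_classes, path = path)
}
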