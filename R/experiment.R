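#' Desk-scale experiment configuration
#'
#' Composes the data-generation, network, training and attack settings of a
#' seeded train / evaluate / attack / profile pipeline on synthetic scenes.
#' Unknown fields are rejected by construction, so a mistyped setting fails
#' loudly rather than being ignored.
#'
#' @param n_train,n_test Scene counts for the training and held-out sets.
#' @param classes Number of shape classes.
#' @param size Scene side length, pixels.
#' @param net Named list of [snn_config()] overrides (e.g.
#'   `list(x = 8L, K = 4L, attention = FALSE)`).
#' @param train A [train_config()].
#' @param epsilons PGD perturbation budgets to evaluate.
#' @param attack_steps PGD iterations.
#' @param attack_n Held-out samples attacked per budget (capped for
#'   tractability).
#' @param seeds Seed vector; each seed governs its run's data, weights,
#'   shuffling and attack initialization.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_train = 1500L, n_test = 300L, classes = 2L,
                              size = 16L, net = list(),
                              train = train_config(),
                              epsilons = c(10, 20, 40) / 255,
                              attack_steps = 10L, attack_n = 200L,
                              seeds = c(0L, 1L, 2L)) {
  stopifnot(n_train >= classes, n_test >= 1, length(seeds) >= 1)
  allowed <- names(formals(snn_config))
  bad <- setdiff(names(net), allowed)
  if (length(bad)) {
    stop("unknown network config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_train = as.integer(n_train), n_test = as.integer(n_test),
         classes = as.integer(classes), size = as.integer(size),
         net = net, train = train, epsilons = epsilons,
         attack_steps = as.integer(attack_steps),
         attack_n = as.integer(attack_n), seeds = as.integer(seeds)),
    class = "experiment_config"
  )
}

build_net_config <- function(config, attention = NULL, learnable = NULL) {
  args <- config$net
  args$in_size <- config$size
  args$n_class <- config$classes
  if (!is.null(attention)) args$attention <- attention
  if (!is.null(learnable)) args$learnable <- learnable
  do.call(snn_config, args)
}

run_single <- function(config, seed, attention = NULL, learnable = NULL) {
  net_cfg <- build_net_config(config, attention, learnable)
  n_all <- config$n_train + config$n_test
  data <- gen_scene_dataset(n_all, classes = config$classes,
                            size = config$size, seed = seed)
  tr_idx <- seq_len(config$n_train)
  te_idx <- config$n_train + seq_len(config$n_test)
  train_data <- list(x = data$x[, , , tr_idx, drop = FALSE], y = data$y[tr_idx])
  test_x <- data$x[, , , te_idx, drop = FALSE]
  test_y <- data$y[te_idx]
  test_masks <- data$masks[, , te_idx, drop = FALSE]

  model <- snn_model(net_cfg, seed = seed)
  tc <- config$train
  tc$seed <- seed
  fit <- snn_train(model, train_data, tc)
  h <- fit$history

  clean_pred <- snn_predict(fit$model, test_x)
  clean_acc <- mean(clean_pred == test_y)

  na <- min(config$attack_n, length(te_idx))
  ax <- test_x[, , , seq_len(na), drop = FALSE]
  ay <- test_y[seq_len(na)]
  rob <- dplyr::bind_rows(lapply(config$epsilons, function(eps) {
    robust_accuracy(fit$model, ax, ay,
                    pgd_config(eps, steps = config$attack_steps, seed = seed))
  }))

  prof_n <- min(200L, length(te_idx))
  frames <- rep(list(test_x[, , , seq_len(prof_n), drop = FALSE]), net_cfg$K)
  fw <- snn_forward(fit$model, frames)
  trace <- structure(list(Y = fw$Y, FC = fw$FC, maps = fw$maps,
                          spikes = fw$spikes, map_idx = fw$map_idx,
                          n_samples = prof_n,
                          input_density = fw$input_density,
                          config = net_cfg), class = "snn_trace")
  fr <- firing_rates(trace)
  macs <- estimate_macs(trace, fit$model)
  gate_ratio <- if (net_cfg$attention && length(fw$maps) > 0L) {
    attention_gate_ratio(fw$maps[[1L]],
                         test_masks[, , seq_len(prof_n), drop = FALSE])
  } else NA_real_

  list(
    fit = fit,
    metrics = tibble::tibble(
      seed = seed,
      attention = net_cfg$attention,
      learnable = net_cfg$learnable,
      epochs_trained = nrow(h),
      train_accuracy = h$accuracy[nrow(h)],
      clean_accuracy = clean_acc,
      mean_firing_rate = fr$mean,
      macs_total = macs$total,
      params = macs$params,
      gate_ratio = gate_ratio
    ),
    robustness = dplyr::mutate(rob, attention = net_cfg$attention,
                               learnable = net_cfg$learnable)
  )
}

#' Mean attended-gate ratio between object and background pixels
#'
#' On held-out scenes, the mean attention gate over ground-truth object
#' pixels divided by the mean gate over background pixels. Values well
#' above 1 mean the learned attention concentrates on the objects.
#'
#' @param map Batched gate array `(1, H, W, N)` or a single gate matrix.
#' @param masks Logical array `(H, W, N)` (or matrix) of object supports.
#' @return The ratio of means.
#' @export
attention_gate_ratio <- function(map, masks) {
  m <- unclass(map)
  if (is.matrix(m)) m <- array(m, c(1L, dim(m), 1L))
  if (length(dim(masks)) == 2L) masks <- array(masks, c(dim(masks), 1L))
  d <- dim(m)
  g <- array(m, d[2:4])
  mean(g[masks]) / mean(g[!masks])
}

#' Run the full seeded evaluation pipeline
#'
#' For every seed: generate data, train, evaluate clean accuracy, PGD
#' robustness at each budget, firing rate and MAC estimates; aggregate the
#' per-seed metrics as mean and sample standard deviation across seeds.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for checkpoints and metric tables.
#' @param dry_run Validate the configuration and return without computing
#'   or writing anything.
#' @return An object of class `snn_experiment` with `per_seed` and
#'   `robustness` tibbles, a `summary` tibble, and the fitted models.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           dry_run = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (dry_run) return(invisible(config))
  runs <- lapply(config$seeds, function(sd) run_single(config, sd))
  assemble_experiment(config, runs, out_dir)
}

assemble_experiment <- function(config, runs, out_dir = NULL) {
  per_seed <- dplyr::bind_rows(lapply(runs, `[[`, "metrics"))
  robustness <- dplyr::bind_rows(lapply(runs, `[[`, "robustness"))
  summarise_ms <- function(df, keys) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of("seed"),
                                     list(mean = mean,
                                          sd = ~ if (dplyr::n() > 1) stats::sd(.x) else NA_real_)),
                       .groups = "drop")
  }
  summary <- summarise_ms(per_seed, c("attention", "learnable"))
  rob_summary <- summarise_ms(
    dplyr::select(robustness, -dplyr::any_of("n")),
    c("attention", "learnable", "epsilon"))
  out <- structure(
    list(config = config, per_seed = per_seed, robustness = robustness,
         summary = summary, robustness_summary = rob_summary,
         fits = lapply(runs, `[[`, "fit")),
    class = "snn_experiment"
  )
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(exp$config)
  hdr <- sprintf("# config %s seeds %s", hash,
                 paste(exp$config$seeds, collapse = ","))
  write_tab <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = "\t",
                                        row.names = FALSE, quote = FALSE))
  }
  write_tab(exp$per_seed, "metrics.tsv")
  write_tab(exp$robustness, "robustness.tsv")
  for (i in seq_along(exp$fits)) {
    save_snn(exp$fits[[i]],
             file.path(out_dir, sprintf("model_seed%d.rds",
                                        exp$config$seeds[i])))
  }
  invisible(out_dir)
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Two-by-two ablation comparison (attention x learnable)
#'
#' Four seeded runs differing only in the attention and learnable flags,
#' all sharing identical data seeds; both-off is the plain feedforward
#' baseline with fixed thresholds and decay factors.
#'
#' @param config An [experiment_config()].
#' @return An object of class `snn_ablation` with the combined `table`
#'   (accuracy, robustness, firing rate per cell) and the underlying
#'   `snn_experiment` objects.
#' @export
compare_ablations <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- expand.grid(attention = c(FALSE, TRUE), learnable = c(FALSE, TRUE))
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    runs <- lapply(config$seeds, function(sd) {
      run_single(config, sd, attention = grid$attention[i],
                 learnable = grid$learnable[i])
    })
    assemble_experiment(config, runs)
  })
  table <- dplyr::bind_rows(lapply(cells, `[[`, "summary"))
  structure(list(table = table,
                 robustness = dplyr::bind_rows(lapply(cells, `[[`,
                                                      "robustness_summary")),
                 per_seed = dplyr::bind_rows(lapply(cells, `[[`, "per_seed")),
                 cells = cells, config = config),
            class = "snn_ablation")
}

#' @export
print.snn_experiment <- function(x, ...) {
  cat(sprintf("<snn_experiment> %d seed(s)\n", length(x$config$seeds)))
  print(x$summary)
  invisible(x)
}

#' @export
print.snn_ablation <- function(x, ...) {
  cat("<snn_ablation> attention x learnable grid\n")
  print(x$table)
  invisible(x)
}

#' Save / load a model or fit checkpoint
#'
#' A checkpoint is a single-file archive of the named weight arrays plus
#' the configuration block (serialized RDS).
#'
#' @param object A [snn_model()] or [snn_train()] result.
#' @param path Checkpoint path.
#' @return `path` invisibly; `load_snn()` returns the restored object.
#' @export
save_snn <- function(object, path) {
  stopifnot(inherits(object, c("tda_snn", "snn_fit")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_snn
#' @export
load_snn <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, c("tda_snn", "snn_fit")))
  obj
}
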