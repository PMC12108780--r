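# YAML run configuration: sections synth, bank, net, train, weights, seeds.
# Omitted fields take the documented defaults; unknown keys are rejected
# with their full key path.

config_defaults <- function() {
  list(
    synth = unclass(synth_config()),
    bank = list(bands = list(theta = c(4, 7), alpha = c(7, 13),
                             beta = c(13, 32), overall = c(4, 32)),
                order = 3L),
    net = list(F1 = 24L, D = 1L, F2 = 12L, F3 = 32L, C1 = NULL, C2 = 15L,
               C3 = 15L, dropout_p = 0.5, pool = 5L),
    train = unclass(train_config()),
    weights = unclass(loss_weights()),
    seeds = list(1L))
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("config: unknown key '", here, "'", call. = FALSE)
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv)) && is.list(uv) &&
        !key %in% c("bands", "seeds")) {
      defaults[[key]] <- merge_config(dv, uv, here)
    } else {
      defaults[key] <- list(uv)
    }
  }
  defaults
}

#' Load a run configuration from a YAML file
#'
#' Recognized sections: \code{synth} (see [synth_config()]), \code{bank}
#' (\code{bands}: named list of \code{[lo, hi]} pairs; \code{order}),
#' \code{net} (see [network_config()]; data-dependent fields C, T, Nb,
#' n_classes, fs are filled from the dataset at run time), \code{train}
#' (see [train_config()]), \code{weights} (lambda1..3), and \code{seeds}
#' (integer list). Omitted fields take the documented defaults; unknown
#' keys raise an error naming the full key path. An empty file yields all
#' defaults.
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @return A validated \code{run_config} list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_defaults(), user)
  # validate eagerly so bad values fail at load time with a clear message
  do.call(synth_config, cfg$synth)
  do.call(loss_weights, cfg$weights)
  tr <- cfg$train
  tr$stage1_mode <- tr$stage1_mode %||% "cv"
  tr$stage2_scope <- tr$stage2_scope %||% "both"
  do.call(train_config, tr)
  cfg$seeds <- as.integer(unlist(cfg$seeds))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_bank <- function(cfg, fs) {
  filter_bank(cfg$bank$bands, order = cfg$bank$order %||% 3L, fs = fs)
}

config_net <- function(cfg, dataset, Nb) {
  nc <- cfg$net
  network_config(C = dim(dataset$X)[2L], T = dim(dataset$X)[3L], Nb = Nb,
                 n_classes = length(unique(dataset$y)),
                 F1 = nc$F1, D = nc$D, F2 = nc$F2, F3 = nc$F3, C1 = nc$C1,
                 C2 = nc$C2, C3 = nc$C3, dropout_p = nc$dropout_p,
                 pool = nc$pool, fs = dataset$fs)
}

config_train <- function(cfg, seed = NULL) {
  tr <- cfg$train
  tr$stage1_mode <- tr$stage1_mode %||% "cv"
  tr$stage2_scope <- tr$stage2_scope %||% "both"
  if (!is.null(seed)) tr$seed <- as.integer(seed)
  do.call(train_config, tr)
}

# serialize the effective configuration (round-trips through load_config)
config_yaml <- function(cfg) yaml::as.yaml(unclass(cfg))
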