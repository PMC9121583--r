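#' Default run configuration
#'
#' Nested list of every tunable setting with its documented default:
#' filtration (max_dim 3, max_scale NULL = enclosing radius, sparsity NULL =
#' exact Rips), curation (k 100, mode H1+H2, kappa_max 3, scaling none),
#' evaluation (decision tree, 10 repetitions, 20 percent test fraction, CNN
#' hyperparameters), seed and verbosity.
#'
#' @return A named nested list.
#' @export
defaultRunConfig <- function() {
  list(
    filtration = list(max_dim = 3L, max_scale = NULL, sparsity = NULL),
    curation = list(k = 100L, mode = "H1+H2", kappa_max = 3, scaling = "none"),
    evaluation = list(
      model = "decision_tree", reps = 10L, test_frac = 0.2,
      cnn = list(n_filters = 32L, kernel_size = 16L, dropout = 0.25,
                 dense_units = c(128L, 64L), epochs = 50L, batch_size = 32L,
                 learning_rate = 1e-3)),
    seed = 1L,
    verbosity = 1L)
}

mergeConfig <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]])) {
      defaults[[nm]] <- mergeConfig(defaults[[nm]], as.list(user[[nm]]), here)
    } else {
      defaults[nm] <- list(user[[nm]])
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' [defaultRunConfig()].
#'
#' @param path YAML file, or NULL for the defaults.
#' @return A named nested list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  stopIfNot(file.exists(path), paste("config file not found:", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  mergeConfig(cfg, user)
}
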