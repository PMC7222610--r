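MODEL_SCHEMA_VERSION <- 1L

binary_to_list <- function(m) {
  out <- list(
    kind = m$kind, pos_label = m$pos_label, neg_label = m$neg_label,
    lambda = m$lambda, mu = m$mu, sigma2 = m$sigma2, n_train = m$n_train,
    scaler = list(center = as.numeric(m$scaler$center),
                  scale = as.numeric(m$scaler$scale)),
    hidden = list(centers = unname(as.matrix(m$hidden$centers)),
                  widths = as.numeric(m$hidden$widths)),
    info = m$info
  )
  if (m$kind == "kernel") {
    out$support_Xtilde <- unname(as.matrix(m$support_Xtilde))
    out$expansion <- as.numeric(m$expansion)
  } else {
    out$weights <- as.numeric(m$weights)
  }
  out
}

as_matrix_rows <- function(x, ncol_hint = NULL) {
  if (is.matrix(x)) return(x)
  m <- matrix(as.numeric(x), nrow = 1)
  if (!is.null(ncol_hint) && length(x) != ncol_hint) {
    m <- matrix(as.numeric(x), ncol = ncol_hint)
  }
  m
}

binary_from_list <- function(l) {
  widths <- as.numeric(l$hidden$widths)
  hidden <- structure(list(centers = as_matrix_rows(l$hidden$centers),
                           widths = widths, M = length(widths)),
                      class = "hidden_layer")
  m <- list(kind = l$kind, scaler = list(center = as.numeric(l$scaler$center),
                                         scale = as.numeric(l$scaler$scale)),
            hidden = hidden, sigma2 = l$sigma2, lambda = l$lambda, mu = l$mu,
            pos_label = l$pos_label, neg_label = l$neg_label,
            n_train = l$n_train, info = l$info)
  if (l$kind == "kernel") {
    m$support_Xtilde <- as_matrix_rows(l$support_Xtilde, hidden$M)
    m$expansion <- as.numeric(l$expansion)
  } else {
    m$weights <- as.numeric(l$weights)
  }
  structure(m, class = "fast_rbf_binary")
}

#' Save a trained model to a JSON archive
#'
#' Single self-describing JSON file holding hyperparameters, labels,
#' standardization constants, hidden-layer arrays and expansion
#' coefficients, with a versioned schema field. Works for both binary
#' and one-vs-one models.
#'
#' @param model A `fast_rbf_binary` or `fast_rbf_ovo`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "fast_rbf_binary")) {
    obj <- list(schema_version = MODEL_SCHEMA_VERSION, type = "binary",
                model = binary_to_list(model))
  } else if (inherits(model, "fast_rbf_ovo")) {
    obj <- list(schema_version = MODEL_SCHEMA_VERSION, type = "ovo",
                tie_break = model$tie_break,
                clf_AB = binary_to_list(model$clf_AB),
                clf_AC = binary_to_list(model$clf_AC),
                clf_BC = binary_to_list(model$clf_BC))
  } else stop("not a fastrbf model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path JSON archive path.
#' @return A `fast_rbf_binary` or `fast_rbf_ovo`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version > MODEL_SCHEMA_VERSION) {
    stop("unsupported model schema version")
  }
  if (identical(obj$type, "binary")) return(binary_from_list(obj$model))
  if (identical(obj$type, "ovo")) {
    return(structure(list(clf_AB = binary_from_list(obj$clf_AB),
                          clf_AC = binary_from_list(obj$clf_AC),
                          clf_BC = binary_from_list(obj$clf_BC),
                          tie_break = obj$tie_break),
                     class = "fast_rbf_ovo"))
  }
  stop("unknown model type in archive")
}
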