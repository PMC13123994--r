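# Single-file model checkpoints: named tensors plus configuration,
# serialized as JSON so checkpoints stay text and portable.

#' Save a fitted model to a JSON checkpoint
#'
#' @param object A fitted \code{epigcn} model.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "epigcn"))
  tensors <- lapply(object$params, function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = length(x), data = as.numeric(x))
  })
  jsonlite::write_json(
    list(format = "epigcn-checkpoint-1",
         dims = unclass(object$dims),
         n_mlp = attr(object$params, "n_mlp"),
         threshold = object$threshold,
         config = object$config,
         tensors = tensors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [write_checkpoint()].
#' @return An \code{epigcn} model usable with [predict.epigcn()].
#' @export
read_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(ck$format) || ck$format != "epigcn-checkpoint-1")
    stop("not an epigcn checkpoint: ", path)
  params <- lapply(ck$tensors, function(t) {
    if (length(t$dim) == 2) matrix(t$data, t$dim[1], t$dim[2])
    else as.numeric(t$data)
  })
  attr(params, "n_mlp") <- ck$n_mlp
  class(params) <- "epigcn_params"
  dims <- ck$dims
  class(dims) <- "epigcn_dims"
  structure(list(params = params, dims = dims,
                 threshold = ck$threshold, loss_trace = numeric(0),
                 val_trace = numeric(0), val_eval = NULL,
                 config = ck$config, n_proteins = NA_integer_),
            class = "epigcn")
}
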