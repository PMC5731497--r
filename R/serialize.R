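# Model container: a trained stacked network together with its encoding
# scheme and decision threshold, stored as JSON at full double precision so
# a round-trip load reproduces predictions bitwise.

#' Save / load a trained model
#'
#' @param network A \code{stacked_network}.
#' @param scheme The \code{encoding_scheme} the network was trained with.
#' @param path File path (JSON).
#' @return \code{load_model} returns a list with \code{network} and
#'   \code{scheme}.
#' @export
save_model <- function(network, scheme, path) {
  stopifnot(inherits(network, "stacked_network"),
            inherits(scheme, "encoding_scheme"))
  obj <- list(
    format = "lincae-model",
    version = 1L,
    scheme = list(name = scheme$name, unit = scheme$unit,
                  table = as.list(scheme$table),
                  scale = scheme$scale),
    d_input = network$d_input,
    threshold = network$threshold,
    layers = lapply(network$layers, function(l)
      list(W = l$W, W_prime = l$W_prime, b_h = l$b_h, b_x = l$b_x,
           s_f = l$s_f, s_g = l$s_g)),
    output = network$output
  )
  # 17 significant digits: lossless text round-trip for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "lincae-model"))
    stop("not a lincae model file: ", path)
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.numeric(unlist(r))))
  tab <- vapply(obj$scheme$table, as.numeric, numeric(1L))
  scheme <- build_scheme("CUSTOM", overrides = tab, unit = obj$scheme$unit,
                         scale = if (!is.null(obj$scheme$scale))
                           as.numeric(unlist(obj$scheme$scale)))
  scheme$name <- obj$scheme$name
  layers <- lapply(obj$layers, function(l)
    ae_layer(as_mat(l$W), as_mat(l$W_prime),
             as.numeric(unlist(l$b_h)), as.numeric(unlist(l$b_x)),
             l$s_f, l$s_g))
  network <- structure(list(layers = layers,
                            output = list(w = as.numeric(unlist(obj$output$w)),
                                          b = as.numeric(obj$output$b)),
                            threshold = as.numeric(obj$threshold),
                            d_input = as.integer(obj$d_input),
                            pretrain_trace = NULL, finetune_trace = NULL),
                       class = "stacked_network")
  list(network = network, scheme = scheme)
}
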