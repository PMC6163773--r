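#' Save a model to a portable JSON container
#'
#' Serializes the package's model objects ([gmm_density()],
#' `reservoir_transform`, [activity_hmm()], [recognizer_bundle()]) as a
#' JSON document: a `type` header, metadata, and all numeric arrays as
#' C99 hexadecimal floating-point strings, so a load reproduces the model
#' bit-exactly.
#'
#' @param model The model object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- encode_model(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path File path.
#' @return The reconstructed model object.
#' @export
load_model <- function(path) {
  decode_model(jsonlite::read_json(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE))
}

# Numeric payloads as hex-float strings: exact and portable.
enc_num <- function(x) {
  if (is.null(x)) return(NULL)
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       hex = sprintf("%a", as.numeric(x)))
}
dec_num <- function(obj) {
  if (is.null(obj)) return(NULL)
  v <- as.numeric(obj$hex)
  if (length(obj$dim) == 2) matrix(v, obj$dim[1], obj$dim[2]) else v
}

encode_model <- function(model) {
  if (inherits(model, "gmm_density")) {
    list(type = "gmm_density", feature_set = model$feature_set,
         weights = enc_num(model$weights), means = enc_num(model$means),
         variances = enc_num(model$variances))
  } else if (inherits(model, "reservoir_transform")) {
    list(type = "reservoir_transform", K = model$K, L = model$L,
         SR = model$SR, input_scaling = model$input_scaling,
         regularization = model$regularization, washout = model$washout,
         seed = model$seed, Win = enc_num(model$Win),
         Wres = enc_num(model$Wres), Wout = enc_num(model$Wout))
  } else if (inherits(model, "activity_hmm")) {
    list(type = "activity_hmm", topology = model$topology,
         label = model$label, feature_set = model$feature_set,
         A = enc_num(model$A), pi = enc_num(model$pi_),
         emissions = lapply(model$emissions, function(e)
           list(weights = enc_num(e$weights), means = enc_num(e$means),
                variances = enc_num(e$variances))))
  } else if (inherits(model, "recognizer_bundle")) {
    list(type = "recognizer_bundle", mode = model$mode,
         selection = model$selection,
         background = if (is.null(model$background)) NULL else
           encode_model(model$background),
         classes = names(model$models),
         models = lapply(model$models, encode_model))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
}

decode_model <- function(obj) {
  switch(obj$type,
    gmm_density = gmm_density(dec_num(obj$weights), dec_num(obj$means),
                              dec_num(obj$variances), obj$feature_set),
    reservoir_transform = {
      rt <- init_reservoir(obj$K, 0L, SR = obj$SR,
                           input_scaling = obj$input_scaling,
                           seed = obj$seed,
                           regularization = obj$regularization,
                           washout = obj$washout)
      rt$L <- as.integer(obj$L)
      rt$Win <- if (obj$L > 0) dec_num(obj$Win) else matrix(0, 0, obj$K)
      rt$Wres <- if (obj$L > 0) dec_num(obj$Wres) else matrix(0, 0, 0)
      rt$Wout <- dec_num(obj$Wout)
      rt
    },
    activity_hmm = activity_hmm(
      dec_num(obj$A), dec_num(obj$pi),
      lapply(obj$emissions, function(e)
        list(weights = dec_num(e$weights), means = dec_num(e$means),
             variances = dec_num(e$variances))),
      topology = obj$topology,
      label = obj$label, feature_set = obj$feature_set),
    recognizer_bundle = {
      models <- lapply(obj$models, decode_model)
      names(models) <- obj$classes
      recognizer_bundle(models, obj$mode,
                        background = if (is.null(obj$background)) NULL else
                          decode_model(obj$background),
                        selection = obj$selection)
    },
    stop("unknown container type: ", obj$type)
  )
}
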