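# Architecture registry for the Mix-Transformer (MiT) encoder family and the
# all-MLP decoder head, plus exact trainable-parameter accounting.
#
# The four registered variants share one architecture and differ only in
# per-stage depths and channel widths. Published per-variant totals pin the
# remaining choices: qkv projections carry biases, the Mix-FFN 3x3
# convolution is depthwise with expansion factor 4, spatial reduction is a
# strided projection (kernel = stride = R) followed by layer normalisation,
# and each stage ends with a layer normalisation.

.mit_registry <- list(
  "mit-b0" = list(depths = c(2L, 2L, 2L, 2L),
                  hidden_dims = c(32L, 64L, 160L, 256L)),
  "mit-b2" = list(depths = c(3L, 4L, 6L, 3L),
                  hidden_dims = c(64L, 128L, 320L, 512L)),
  "mit-b3" = list(depths = c(3L, 4L, 18L, 3L),
                  hidden_dims = c(64L, 128L, 320L, 512L)),
  "mit-b5" = list(depths = c(3L, 6L, 40L, 3L),
                  hidden_dims = c(64L, 128L, 320L, 512L))
)

#' Resolve a Mix-Transformer model specification
#'
#' Looks up one of the registered encoder variants (`"mit-b0"`, `"mit-b2"`,
#' `"mit-b3"`, `"mit-b5"`), applies any field overrides (as used in the
#' ablation experiments, e.g. different attention heads or hidden widths),
#' and validates the result.
#'
#' @param name registered model identifier.
#' @param overrides named list of spec fields replacing registry defaults;
#'   unknown field names are an error.
#' @return a validated `mit_spec` object: a named list with fields `name`,
#'   `depths`, `attention_heads`, `hidden_dims`, `sr_ratios`,
#'   `merge_kernels`, `merge_strides`, `merge_paddings`, `mlp_ratio`,
#'   `decoder_dim`, `num_classes`, `dropout`, `layer_norm_eps`.
#' @examples
#' spec <- resolve_spec("mit-b0")
#' spec$hidden_dims
#' big_heads <- resolve_spec("mit-b0",
#'                           list(attention_heads = c(2L, 4L, 10L, 16L)))
#' @export
resolve_spec <- function(name, overrides = list()) {
  if (!name %in% names(.mit_registry)) {
    stop("unknown model '", name, "'; registered: ",
         paste(names(.mit_registry), collapse = ", "))
  }
  reg <- .mit_registry[[name]]
  spec <- list(
    name = name,
    depths = reg$depths,
    attention_heads = c(1L, 2L, 5L, 8L),
    hidden_dims = reg$hidden_dims,
    sr_ratios = c(8L, 4L, 2L, 1L),
    merge_kernels = c(7L, 3L, 3L, 3L),
    merge_strides = c(4L, 2L, 2L, 2L),
    merge_paddings = c(3L, 1L, 1L, 1L),
    mlp_ratio = 4L,
    decoder_dim = 256L,
    num_classes = 12L,
    dropout = 0.1,
    layer_norm_eps = 1e-6
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(spec))
    if (length(bad)) stop("unknown spec field(s): ", paste(bad, collapse = ", "))
    for (f in names(overrides)) spec[[f]] <- overrides[[f]]
  }
  validate_spec(spec)
}

#' Validate a model specification
#'
#' Checks the structural invariants that the architecture relies on and
#' returns the spec with class `mit_spec`. Violations raise an error naming
#' the failed invariant.
#'
#' @param spec a spec list as produced by [resolve_spec()].
#' @return the validated spec, classed `mit_spec`.
#' @export
validate_spec <- function(spec) {
  vec4 <- c("depths", "attention_heads", "hidden_dims", "sr_ratios",
            "merge_kernels", "merge_strides", "merge_paddings")
  for (f in vec4) {
    v <- spec[[f]]
    if (length(v) != 4L || any(v != as.integer(v)))
      stop("invariant violated: ", f, " must be 4 integers")
    spec[[f]] <- as.integer(v)
  }
  if (any(spec$depths < 1L) || any(spec$attention_heads < 1L) ||
      any(spec$hidden_dims < 1L) || any(spec$sr_ratios < 1L))
    stop("invariant violated: depths, heads, dims and sr_ratios must be positive")
  if (any(spec$hidden_dims %% spec$attention_heads != 0L))
    stop("invariant violated: hidden_dims must be divisible by attention_heads ",
         "(head dim = C_i / N_i); offending stage(s): ",
         paste(which(spec$hidden_dims %% spec$attention_heads != 0L),
               collapse = ", "))
  if (any(diff(spec$hidden_dims) <= 0L))
    stop("invariant violated: hidden_dims must be strictly increasing across stages")
  if (prod(spec$merge_strides) != 32L)
    stop("invariant violated: product of merge_strides must be 32 ",
         "(final feature at 1/32 resolution)")
  if (any(diff(spec$sr_ratios) > 0L))
    stop("invariant violated: sr_ratios must be non-increasing across stages")
  if (any(spec$merge_kernels < spec$merge_strides))
    stop("invariant violated: merge kernel must be >= stride (overlap)")
  if (spec$mlp_ratio < 1L) stop("invariant violated: mlp_ratio must be positive")
  if (spec$decoder_dim < 1L) stop("invariant violated: decoder_dim must be positive")
  if (spec$num_classes < 1L) stop("invariant violated: num_classes must be positive")
  if (spec$dropout < 0 || spec$dropout > 1)
    stop("invariant violated: dropout must be in [0,1]")
  if (spec$layer_norm_eps <= 0)
    stop("invariant violated: layer_norm_eps must be positive")
  structure(spec, class = "mit_spec")
}

#' @export
print.mit_spec <- function(x, ...) {
  cat("Mix-Transformer spec:", x$name, "\n")
  cat("  depths         ", paste(x$depths, collapse = ","), "\n")
  cat("  attention heads", paste(x$attention_heads, collapse = ","), "\n")
  cat("  hidden dims    ", paste(x$hidden_dims, collapse = ","), "\n")
  cat("  sr ratios      ", paste(x$sr_ratios, collapse = ","), "\n")
  cat("  merge K/S/P    ", paste(x$merge_kernels, collapse = ","), "/",
      paste(x$merge_strides, collapse = ","), "/",
      paste(x$merge_paddings, collapse = ","), "\n")
  cat("  mlp ratio", x$mlp_ratio, " decoder dim", x$decoder_dim,
      " classes", x$num_classes, "\n")
  invisible(x)
}

## ---- parameter shape manifest ----------------------------------------------

# The single source of truth for which trainable arrays exist and their
# shapes; weight initialisation and parameter counting both consume it.
param_shapes <- function(spec, scope = c("full", "encoder", "decoder")) {
  scope <- match.arg(scope)
  shapes <- list()
  if (scope %in% c("full", "encoder")) {
    c_in <- 3L
    for (i in 1:4) {
      C <- spec$hidden_dims[i]
      K <- spec$merge_kernels[i]
      R <- spec$sr_ratios[i]
      m <- spec$mlp_ratio
      pre <- sprintf("enc.s%d.", i)
      shapes[[paste0(pre, "embed.W")]] <- c(K * K * c_in, C)
      shapes[[paste0(pre, "embed.b")]] <- C
      shapes[[paste0(pre, "embed.g")]] <- C
      shapes[[paste0(pre, "embed.be")]] <- C
      for (j in seq_len(spec$depths[i])) {
        bp <- sprintf("%sb%d.", pre, j)
        shapes[[paste0(bp, "norm1.g")]] <- C
        shapes[[paste0(bp, "norm1.b")]] <- C
        for (w in c("Wq", "Wk", "Wv", "Wo")) {
          shapes[[paste0(bp, "attn.", w)]] <- c(C, C)
        }
        for (b in c("bq", "bk", "bv", "bo")) {
          shapes[[paste0(bp, "attn.", b)]] <- C
        }
        if (R > 1L) {
          shapes[[paste0(bp, "attn.Wsr")]] <- c(R * R * C, C)
          shapes[[paste0(bp, "attn.bsr")]] <- C
          shapes[[paste0(bp, "attn.srnorm.g")]] <- C
          shapes[[paste0(bp, "attn.srnorm.b")]] <- C
        }
        shapes[[paste0(bp, "norm2.g")]] <- C
        shapes[[paste0(bp, "norm2.b")]] <- C
        shapes[[paste0(bp, "ffn.W1")]] <- c(C, m * C)
        shapes[[paste0(bp, "ffn.b1")]] <- m * C
        shapes[[paste0(bp, "ffn.Wdw")]] <- c(3L, 3L, m * C)
        shapes[[paste0(bp, "ffn.bdw")]] <- m * C
        shapes[[paste0(bp, "ffn.W2")]] <- c(m * C, C)
        shapes[[paste0(bp, "ffn.b2")]] <- C
      }
      shapes[[paste0(pre, "norm.g")]] <- C
      shapes[[paste0(pre, "norm.b")]] <- C
      c_in <- C
    }
  }
  if (scope %in% c("full", "decoder")) {
    Cd <- spec$decoder_dim
    for (i in 1:4) {
      shapes[[sprintf("dec.lin%d.W", i)]] <- c(spec$hidden_dims[i], Cd)
      shapes[[sprintf("dec.lin%d.b", i)]] <- Cd
    }
    shapes[["dec.fuse.W"]] <- c(4L * Cd, Cd)
    shapes[["dec.fuse.b"]] <- Cd
    shapes[["dec.cls.W"]] <- c(Cd, spec$num_classes)
    shapes[["dec.cls.b"]] <- spec$num_classes
  }
  shapes
}

#' Count trainable parameters
#'
#' Enumerates every trainable array of the instantiated network for the
#' requested scope and sums their sizes. The count depends only on the
#' architecture, never on the input image size.
#'
#' @param spec a validated `mit_spec`.
#' @param scope `"encoder"`, `"decoder"` or `"full"`.
#' @return integer-valued count of trainable scalar weights.
#' @examples
#' count_parameters(resolve_spec("mit-b2"), "encoder")  # 24,196,288
#' @export
count_parameters <- function(spec, scope = c("full", "encoder", "decoder")) {
  scope <- match.arg(scope)
  spec <- validate_spec(spec)
  sum(vapply(param_shapes(spec, scope), prod, numeric(1)))
}

#' Initialise trainable weights
#'
#' Allocates every trainable array of the network (Glorot-normal matrices,
#' unit layer-norm gains, zero biases) under the given seed.
#'
#' @param spec a validated `mit_spec`.
#' @param scope which part of the network to instantiate.
#' @param seed integer RNG seed.
#' @return named list of numeric arrays (the flat checkpoint container).
#' @export
init_params <- function(spec, scope = c("full", "encoder", "decoder"),
                        seed = 1L) {
  scope <- match.arg(scope)
  spec <- validate_spec(spec)
  shapes <- param_shapes(spec, scope)
  set.seed(seed)
  params <- vector("list", length(shapes))
  names(params) <- names(shapes)
  for (k in names(shapes)) {
    s <- shapes[[k]]
    leaf <- sub(".*\\.", "", k)
    if (leaf %in% c("g")) {
      params[[k]] <- rep(1, s)
    } else if (leaf %in% c("b", "be", "bq", "bk", "bv", "bo", "bsr",
                           "b1", "bdw", "b2")) {
      params[[k]] <- rep(0, s)
    } else if (length(s) == 1L) {
      params[[k]] <- rep(0, s)
    } else {
      fan_in <- prod(s[-length(s)])
      fan_out <- s[length(s)]
      sd <- sqrt(2 / (fan_in + fan_out))
      params[[k]] <- array(rnorm(prod(s), sd = sd), s)
    }
  }
  params
}

## ---- spec serialisation -----------------------------------------------------

#' Write / read a model spec as a plain-text config file
#'
#' YAML (`.yml`/`.yaml`) or JSON (anything else). The round trip is lossless.
#'
#' @param spec a validated `mit_spec`.
#' @param path file path; extension selects the format.
#' @return `write_spec` returns `path` invisibly; `read_spec` returns the
#'   validated `mit_spec`.
#' @export
write_spec <- function(spec, path) {
  x <- unclass(spec)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 17L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_spec(x)
}
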