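#' Capacity ledger for the four architectures
#'
#' Each architecture's capacity is set by a pair `(H, U)`: `H` sizes the
#' characteristic first layer (hidden units for the MLP, attention heads for
#' Att, LSTM hidden units per direction, CNN feature maps) and `U` is the
#' width of the second-to-last linear layer. Six capacity levels are indexed
#' by the approximate order of magnitude `log10(C)` of the trainable parameter
#' count `C`.
#'
#' @return A tibble with columns `family`, `level`, `H`, `U`.
#' @export
capacity_table <- function() {
  lv <- c(2.70, 3.00, 3.50, 4.15, 4.75, 5.50)
  tibble::tibble(
    family = rep(c("MLP", "Att", "LSTM", "CNN"), each = 6),
    level = rep(lv, 4),
    H = c(5, 10, 30, 80, 200, 500,
          2, 4, 6, 12, 24, 80,
          2, 3, 4, 10, 16, 48,
          1, 1, 2, 4, 8, 20),
    U = c(5, 10, 30, 80, 200, 500,
          9, 12, 24, 60, 120, 180,
          5, 8, 18, 35, 78, 145,
          1, 2, 4, 9, 16, 36)
  )
}

#' Look up the `(H, U)` pair for a family and capacity level
#'
#' @param family One of `"MLP"`, `"Att"`, `"LSTM"`, `"CNN"`.
#' @param level One of the six capacity levels `2.70, 3.00, 3.50, 4.15, 4.75,
#'   5.50` (approximate `log10` parameter counts).
#' @return A named list with `H` and `U`.
#' @examples
#' capacity_lookup("MLP", 3.50) # H = 30, U = 30
#' @export
capacity_lookup <- function(family, level) {
  tab <- capacity_table()
  row <- tab[tab$family == family & abs(tab$level - level) < 1e-8, ]
  if (nrow(row) != 1L) {
    stop("unknown capacity level ", level, " for family ", family,
         " (levels: 2.70, 3.00, 3.50, 4.15, 4.75, 5.50)", call. = FALSE)
  }
  list(H = row$H, U = row$U)
}

#' Describe a classifier architecture
#'
#' @param family Architecture family: `"MLP"`, `"Att"`, `"LSTM"` or `"CNN"`.
#' @param level Capacity level from [capacity_table()]; ignored when `H` and
#'   `U` are given explicitly.
#' @param H,U Optional explicit capacity pair overriding the ledger.
#' @param dropout_rate Dropout rate (default 0.1).
#' @param loop_length Apical loop length the input layout assumes (default 4,
#'   giving input length `2 * 10 + 4 = 24`).
#' @param max_len Maximum stem length (default 10).
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(family = c("MLP", "Att", "LSTM", "CNN"),
                              level = NULL, H = NULL, U = NULL,
                              dropout_rate = 0.1, loop_length = 4,
                              max_len = max_strand_length()) {
  family <- match.arg(family)
  if (is.null(H) || is.null(U)) {
    if (is.null(level)) stop("give either `level` or both `H` and `U`", call. = FALSE)
    hu <- capacity_lookup(family, level)
    H <- hu$H
    U <- hu$U
  }
  stopifnot(H >= 1, U >= 1)
  structure(
    list(family = family, level = level, H = as.integer(H), U = as.integer(U),
         dropout_rate = dropout_rate, embedding_dim = 4L,
         input_length = as.integer(2L * max_len + loop_length),
         loop_length = as.integer(loop_length), max_len = as.integer(max_len)),
    class = "architecture_spec")
}

## ---- initialisation -------------------------------------------------------
## Linear and convolution weights use the uniform fan-in rule
## U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for weights and biases; LSTM parameters
## use U(-1/sqrt(H), 1/sqrt(H)); attention projections use Xavier-uniform;
## embeddings are standard normal with the PAD row frozen at zero.

init_linear <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  list(W = matrix(runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = runif(fan_out, -b, b))
}

init_xavier <- function(fan_in, fan_out) {
  b <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = rep(0, fan_out))
}

init_bn <- function(f) list(gamma = rep(1, f), beta = rep(0, f))

bn_state <- function(f) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, f)
  st$var <- rep(1, f)
  st
}

init_embedding <- function() {
  W <- matrix(rnorm(20), 5, 4)
  W[1, ] <- 0 # PAD embeds to the zero vector
  W
}

# sinusoidal positional encoding, model dimension 4
positional_encoding <- function(T, d = 4L) {
  pe <- matrix(0, T, d)
  pos <- seq_len(T) - 1
  for (i in seq_len(d %/% 2)) {
    freq <- 1 / 10000^(2 * (i - 1) / d)
    pe[, 2 * i - 1] <- sin(pos * freq)
    pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}

#' Build a classifier model
#'
#' Constructs one of the four architectures with freshly initialised
#' parameters. All models embed tokens into 4 dimensions (PAD frozen at the
#' zero vector), apply a characteristic first layer, then share a two-layer
#' head of the form linear--batchnorm--ReLU--dropout--linear--sigmoid:
#'
#' * `MLP`: flattened embedding, then linear(H)--batchnorm--ReLU--dropout.
#' * `Att`: sinusoidal positional encodings added to the embeddings, a
#'   kernel-1 convolution projecting 4 to H channels, then a residual
#'   multi-head self-attention block with H one-dimensional heads,
#'   `batchnorm(h1 + dropout(self_attention(h1)))`, flattened per position.
#' * `LSTM`: a one-layer bidirectional LSTM with H hidden units per direction
#'   (no internal dropout), per-position outputs flattened.
#' * `CNN`: an outer concatenation mapping the `24 x 4` embedded matrix to a
#'   `24 x 24 x 8` tensor (position `(i, j)` holds the concatenated encodings
#'   of positions `i` and `j`), a `3 x 3` convolution (stride 1, padding 1)
#'   with H feature maps, batchnorm--ReLU--dropout, flattened.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed; the same `(spec, seed)` always gives identical
#'   initial parameters.
#' @return A `hairpin_model` object.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(seed)
  Tlen <- spec$input_length
  H <- spec$H
  U <- spec$U
  params <- list(embedding = init_embedding())
  bn <- list()
  add_linear <- function(name, fi, fo) {
    l <- init_linear(fi, fo)
    params[[paste0(name, "_W")]] <<- l$W
    params[[paste0(name, "_b")]] <<- l$b
  }
  add_bn <- function(name, f) {
    g <- init_bn(f)
    params[[paste0(name, "_gamma")]] <<- g$gamma
    params[[paste0(name, "_beta")]] <<- g$beta
    bn[[name]] <<- bn_state(f)
  }
  head_in <- switch(spec$family,
    MLP = {
      add_linear("l1", Tlen * 4L, H)
      add_bn("bn1", H)
      H
    },
    Att = {
      add_linear("conv1", 4L, H)
      for (nm in c("q", "k", "v")) {
        x <- init_xavier(H, H)
        params[[paste0(nm, "_W")]] <- x$W
        params[[paste0(nm, "_b")]] <- x$b
      }
      add_linear("o", H, H)
      add_bn("bn1", H)
      Tlen * H
    },
    LSTM = {
      b <- 1 / sqrt(H)
      for (d in c("f", "r")) {
        params[[paste0("Wih_", d)]] <- matrix(runif(4L * 4L * H, -b, b), 4L, 4L * H)
        params[[paste0("Whh_", d)]] <- matrix(runif(H * 4L * H, -b, b), H, 4L * H)
        params[[paste0("bih_", d)]] <- runif(4L * H, -b, b)
        params[[paste0("bhh_", d)]] <- runif(4L * H, -b, b)
      }
      Tlen * 2L * H
    },
    CNN = {
      add_linear("conv1", 72L, H) # 3x3 kernel over 8 input channels
      add_bn("bn1", H)
      Tlen * Tlen * H
    })
  add_linear("l2", head_in, U)
  add_bn("bn2", U)
  add_linear("l3", U, 1L)
  structure(
    list(spec = spec, params = params, bn = bn, seed = seed,
         pe = if (spec$family == "Att") positional_encoding(Tlen) else NULL),
    class = "hairpin_model")
}

#' @export
print.hairpin_model <- function(x, ...) {
  cat(sprintf("<hairpin_model> %s (H = %d, U = %d), %d trainable parameters\n",
              x$spec$family, x$spec$H, x$spec$U, count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts every learnable value in the model, including the nucleotide
#' embedding but excluding the frozen PAD embedding row.
#'
#' @param model A `hairpin_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  total <- sum(vapply(model$params, length, numeric(1)))
  as.integer(total - 4L) # PAD embedding row is frozen
}

## ---- forward graphs -------------------------------------------------------

# builds the computation graph for a batch of token rows; returns the tape,
# the output node and the parameter leaf nodes (named like model$params)
forward_graph <- function(model, tokens, training = FALSE) {
  spec <- model$spec
  tape <- tape_new(training)
  P <- lapply(model$params, function(p) tp_leaf(tape, p))
  B <- nrow(tokens)
  Tlen <- ncol(tokens)
  if (Tlen != spec$input_length) {
    stop("token length ", Tlen, " does not match model input length ",
         spec$input_length, call. = FALSE)
  }
  drop <- spec$dropout_rate
  emb <- tp_embed(tape, as.integer(tokens), P$embedding) # (B*T) x 4
  lin <- function(x, nm) tp_addbias(tape, tp_matmul(tape, x, P[[paste0(nm, "_W")]]),
                                    P[[paste0(nm, "_b")]])
  bnorm <- function(x, nm) tp_batchnorm(tape, x, P[[paste0(nm, "_gamma")]],
                                        P[[paste0(nm, "_beta")]], model$bn[[nm]])
  body <- switch(spec$family,
    MLP = {
      x <- tp_reshape(tape, emb, c(B, Tlen * 4L))
      x <- tp_dropout(tape, tp_relu(tape, bnorm(lin(x, "l1"), "bn1")), drop)
      x
    },
    Att = {
      pe_rows <- model$pe[rep(seq_len(Tlen), each = B), , drop = FALSE]
      x <- tp_addconst(tape, emb, pe_rows)
      h1 <- lin(x, "conv1") # kernel-1 convolution = position-wise linear
      att <- tp_mhsa(tape, lin(h1, "q"), lin(h1, "k"), lin(h1, "v"), B, Tlen)
      h2 <- bnorm(tp_add(tape, h1, tp_dropout(tape, lin(att, "o"), drop)), "bn1")
      tp_reshape(tape, h2, c(B, Tlen * spec$H))
    },
    LSTM = {
      H <- spec$H
      run_dir <- function(d, order) {
        h <- tp_leaf(tape, matrix(0, B, H))
        cc <- tp_leaf(tape, matrix(0, B, H))
        out <- vector("list", Tlen)
        for (t in order) {
          xt <- tp_rows(tape, emb, ((t - 1L) * B + 1L):(t * B))
          gates <- tp_addbias(tape, tp_addbias(tape,
            tp_add(tape, tp_matmul(tape, xt, P[[paste0("Wih_", d)]]),
                   tp_matmul(tape, h, P[[paste0("Whh_", d)]])),
            P[[paste0("bih_", d)]]), P[[paste0("bhh_", d)]])
          ig <- tp_sigmoid(tape, tp_cols(tape, gates, 1:H))
          fg <- tp_sigmoid(tape, tp_cols(tape, gates, (H + 1):(2 * H)))
          gg <- tp_tanh(tape, tp_cols(tape, gates, (2 * H + 1):(3 * H)))
          og <- tp_sigmoid(tape, tp_cols(tape, gates, (3 * H + 1):(4 * H)))
          cc <- tp_add(tape, tp_mul(tape, fg, cc), tp_mul(tape, ig, gg))
          h <- tp_mul(tape, og, tp_tanh(tape, cc))
          out[[t]] <- h
        }
        tp_stack_rows(tape, out)
      }
      both <- tp_cbind(tape, run_dir("f", seq_len(Tlen)),
                       run_dir("r", rev(seq_len(Tlen))))
      tp_reshape(tape, both, c(B, Tlen * 2L * H))
    },
    CNN = {
      idx <- cnn_index_maps(B, Tlen)
      BP <- B * Tlen * Tlen
      # outer concatenation: grid position p = i + (j-1)*T holds the
      # concatenated encodings of sequence positions i and j
      z <- tp_cbind(tape, tp_gather_rows(tape, emb, idx$rows_i),
                    tp_gather_rows(tape, emb, idx$rows_j)) # (B*T^2) x 8
      # im2col for the 3x3 convolution with zero padding on the T x T grid
      zaug <- tp_pad_row(tape, z)
      col <- tp_reshape(tape, tp_gather_rows(tape, zaug, idx$ridx),
                        c(BP, 72L))
      x <- tp_dropout(tape, tp_relu(tape, bnorm(lin(col, "conv1"), "bn1")), drop)
      tp_reshape(tape, x, c(B, Tlen * Tlen * spec$H))
    })
  x <- tp_dropout(tape, tp_relu(tape, bnorm(lin(body, "l2"), "bn2")), drop)
  y <- tp_sigmoid(tape, lin(x, "l3"))
  list(tape = tape, y = y, params = P)
}

# gather-index maps for the CNN's outer concatenation and im2col, cached per
# (batch size, input length) since building them costs more than using them
.idx_cache <- new.env(parent = emptyenv())

cnn_index_maps <- function(B, T) {
  key <- paste0(B, "_", T)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- T * T
  BP <- B * P
  i_of_p <- rep(seq_len(T), times = T)
  j_of_p <- rep(seq_len(T), each = T)
  base <- rep(seq_len(B), times = P)
  rows_for <- function(pos) base + rep((pos - 1L) * B, each = B)
  nb <- conv_neighbours(T)
  ridx <- matrix(0L, BP, 9L)
  for (k in 1:9) {
    pk <- rep(nb[, k], each = B)
    rk <- base + (pk - 1L) * B
    rk[pk == 0L] <- BP + 1L # the appended all-zero padding row
    ridx[, k] <- rk
  }
  out <- list(rows_i = rows_for(i_of_p), rows_j = rows_for(j_of_p),
              ridx = as.vector(ridx))
  .idx_cache[[key]] <- out
  out
}

# 3x3 neighbourhood map on a T x T grid (column-major p = i + (j-1)*T);
# 0 marks out-of-grid (zero-padded) neighbours
conv_neighbours <- function(T) {
  i_of_p <- rep(seq_len(T), times = T)
  j_of_p <- rep(seq_len(T), each = T)
  nb <- matrix(0L, T * T, 9L)
  k <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      k <- k + 1L
      ii <- i_of_p + di
      jj <- j_of_p + dj
      ok <- ii >= 1L & ii <= T & jj >= 1L & jj <= T
      nb[ok, k] <- ii[ok] + (jj[ok] - 1L) * T
    }
  }
  nb
}

#' Positivity scores for encoded examples
#'
#' Runs the model in evaluation mode (dropout off, batch normalisation using
#' running statistics) and returns one score in `(0, 1)` per example,
#' preserving input order.
#'
#' @param model A `hairpin_model` (typically from a fitted object).
#' @param tokens Integer token matrix from [encode_dataset()], or a
#'   `hairpin_dataset` (encoded on the fly).
#' @param batch_size Evaluation batch size; defaults to 4096, except 256 for
#'   the CNN whose outer-concatenation tensor grows 576-fold with the batch.
#' @return Numeric vector of positivity scores.
#' @export
predict_scores <- function(model, tokens, batch_size = NULL) {
  if (is.data.frame(tokens)) tokens <- encode_dataset(tokens, model$spec$max_len)
  if (is.null(batch_size)) {
    batch_size <- if (model$spec$family == "CNN") 256L else 4096L
  }
  n <- nrow(tokens)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fg <- forward_graph(model, tokens[idx, , drop = FALSE], training = FALSE)
    out[idx] <- as.numeric(fg$y$val)
  }
  out
}

#' @export
predict.hairpin_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the architecture spec, all parameters and the batch
#' normalisation running statistics in a single file.
#'
#' @param model A `hairpin_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `hairpin_model`.
#' @export
save_model <- function(model, path) {
  bn <- lapply(model$bn, function(st) list(mean = st$mean, var = st$var))
  saveRDS(list(spec = model$spec, params = model$params, bn = bn,
               seed = model$seed), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- readRDS(path)
  bn <- lapply(raw$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$mean <- st$mean
    e$var <- st$var
    e
  })
  structure(
    list(spec = raw$spec, params = raw$params, bn = bn, seed = raw$seed,
         pe = if (raw$spec$family == "Att")
           positional_encoding(raw$spec$input_length) else NULL),
    class = "hairpin_model")
}
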