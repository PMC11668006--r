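#' Model configuration for the neural token classifier
#'
#' Defaults follow the de-identification setup used throughout the package:
#' 5 fine-tuning epochs, learning rate 1e-5 with Adam, categorical
#' cross-entropy, a privacy-conservative decision rule (a token is labelled
#' NON-NAME only when its NON-NAME probability strictly exceeds
#' `non_name_threshold`, default 0.9 — ties and uncertainty fall to NAME),
#' and a 512-unit sequence limit with longer narratives split into
#' independent chunks.
#'
#' Two backends share one interface. `tiny_test_transformer` is the
#' self-contained backend implemented in this package: a single-layer,
#' single-head self-attention encoder over hashed word-piece embeddings plus
#' orthographic shape and position embeddings, small enough to fine-tune in
#' seconds on a CPU. `pretrained_uncased_transformer` names the full-scale
#' variant (a pretrained uncased BERT-class encoder); no pretrained weights
#' ship with this package, so selecting it raises an informative error.
#'
#' @param epochs Number of fine-tuning passes over the corpus (>= 0).
#' @param learning_rate Adam step size.
#' @param non_name_threshold Decision threshold in (0, 1] on the NON-NAME
#'   probability; strictly-greater comparison.
#' @param max_sequence_length Maximum units per chunk, including the two
#'   begin/end sentinels (>= 3).
#' @param seed Integer seed controlling initialization and batch order.
#' @param backend `"tiny_test_transformer"` or
#'   `"pretrained_uncased_transformer"`.
#' @param hidden_size,vocab_size,feature_scale Tiny-backend architecture
#'   knobs: embedding width, hashed word-piece vocabulary size, and the
#'   fixed scale applied to the encoder output before the classification
#'   head (a large scale keeps the head responsive at small learning rates).
#' @return A list of class `model_config`.
#' @export
model_config <- function(epochs = 5L, learning_rate = 1e-5,
                         non_name_threshold = 0.9,
                         max_sequence_length = 512L, seed = 42L,
                         backend = "tiny_test_transformer",
                         hidden_size = 48L, vocab_size = 1024L,
                         feature_scale = 12) {
  backend <- match.arg(backend,
                       c("tiny_test_transformer", "pretrained_uncased_transformer"))
  cfg <- list(epochs = as.integer(epochs), learning_rate = learning_rate,
              non_name_threshold = non_name_threshold,
              max_sequence_length = as.integer(max_sequence_length),
              seed = as.integer(seed), backend = backend,
              hidden_size = as.integer(hidden_size),
              vocab_size = as.integer(vocab_size),
              feature_scale = feature_scale)
  stopifnot(cfg$epochs >= 0L, cfg$learning_rate > 0,
            cfg$non_name_threshold > 0, cfg$non_name_threshold <= 1,
            cfg$max_sequence_length >= 3L, cfg$hidden_size >= 4L,
            cfg$vocab_size >= 16L, cfg$feature_scale > 0)
  class(cfg) <- "model_config"
  cfg
}

# ---- word-piece units (tiny backend) --------------------------------------

N_SPECIAL <- 3L  # 1 = [CLS], 2 = [SEP], 3 = reserved

hash_piece <- function(piece) {
  # deterministic polynomial hash over code points, stays in double range
  h <- 0
  for (c in utf8ToInt(piece)) h <- (h * 31 + c) %% 1048573
  h
}

word_pieces <- function(word) {
  lw <- tolower(word)
  n <- nchar(lw, type = "chars")
  if (n <= 4L) return(lw)
  starts <- seq(1L, n, by = 4L)
  pieces <- substring(lw, starts, pmin(starts + 3L, n))
  c(pieces[1], paste0("##", pieces[-1]))
}

piece_ids <- function(pieces, vocab_size) {
  vapply(pieces, function(p) N_SPECIAL + 1L +
           as.integer(hash_piece(p) %% vocab_size), integer(1),
         USE.NAMES = FALSE)
}

# orthographic shape id per word: 1 + caps*1 + allcaps*2 + digit*4 + short*8
word_shape_id <- function(word) {
  n <- nchar(word, type = "chars")
  caps <- grepl("^\\p{Lu}", word, perl = TRUE)
  allcaps <- n >= 2L && !grepl("[\\p{Ll}\\p{Nd}]", word, perl = TRUE) && caps
  digit <- grepl("\\p{Nd}", word, perl = TRUE)
  shrt <- n <= 3L
  1L + caps * 1L + allcaps * 2L + digit * 4L + shrt * 8L
}

# Encode the words of a narrative as per-word groups of subword unit ids,
# with parallel shape ids. Returns list(ids = list of int vectors,
# shapes = int vector, words = character).
encode_words <- function(words, vocab_size) {
  list(ids = lapply(words, function(w) piece_ids(word_pieces(w), vocab_size)),
       shapes = vapply(words, word_shape_id, integer(1), USE.NAMES = FALSE))
}

#' Split a subword sequence into model-sized chunks
#'
#' Narratives longer than the model's sequence limit are split into
#' non-overlapping, order-preserving chunks that are scored independently.
#' A chunk never splits one word's group of subword units, and each chunk
#' holds at most `max_len` units including the two begin/end sentinels. A
#' single word whose subwords alone exceed the budget has its tail subwords
#' truncated, with a warning.
#'
#' @param groups A list of unit vectors, one per word (or an atomic vector,
#'   treated as one group per unit).
#' @param max_len Chunk capacity including sentinels (>= 3).
#' @return A list of chunks; each chunk is a list of word groups. The
#'   concatenation of all chunk contents equals the input (up to the
#'   warned truncation case).
#' @export
split_sequences <- function(groups, max_len) {
  stopifnot(max_len >= 3L)
  if (is.atomic(groups)) groups <- as.list(groups)
  capacity <- max_len - 2L
  sizes <- lengths(groups)
  over <- sizes > capacity
  if (any(over)) {
    warning(sprintf(
      "%d word(s) exceed the chunk capacity of %d units; tail subwords truncated",
      sum(over), capacity))
    groups[over] <- lapply(groups[over], function(g) g[seq_len(capacity)])
    sizes[over] <- capacity
  }
  lapply(chunk_group_indices(sizes, capacity), function(ix) groups[ix])
}

# greedy packing of word groups (given their unit counts) into chunks of at
# most `capacity` units; returns a list of index vectors
chunk_group_indices <- function(sizes, capacity) {
  chunks <- list()
  cur <- integer(0)
  used <- 0L
  for (i in seq_along(sizes)) {
    if (used + sizes[i] > capacity && used > 0L) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- integer(0); used <- 0L
    }
    cur <- c(cur, i); used <- used + sizes[i]
  }
  if (length(cur) > 0L || length(chunks) == 0L)
    chunks[[length(chunks) + 1L]] <- cur
  chunks
}

# ---- tiny transformer: parameters, forward, backward ----------------------

init_params <- function(cfg) {
  set.seed(cfg$seed)
  d <- cfg$hidden_size
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  list(
    emb = rn(cfg$vocab_size + N_SPECIAL, d, 0.02),
    # shape embeddings are the dominant orthographic signal in this small
    # model, so they start an order of magnitude larger than word pieces
    shape = rn(17L, d, 0.2),
    pos = rn(cfg$max_sequence_length, d, 0.02),
    Wq = rn(d, d, 0.02), Wk = rn(d, d, 0.02),
    Wv = rn(d, d, 0.02), Wo = rn(d, d, 0.02),
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wf1 = rn(d, 4L * d, 0.02), bf1 = rep(0, 4L * d),
    Wf2 = rn(4L * d, d, 0.02), bf2 = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    Wc = rn(d, 2L, 0.005), bc = rep(0, 2L))
}

LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu            # length-nrow vector recycles per row (column-major)
  va <- rowMeans(xc * xc)
  sd <- sqrt(va + LN_EPS)
  xhat <- xc / sd
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(y = y, xhat = xhat, sd = sd, xc = xc)
}

layernorm_bwd <- function(dy, cache, g) {
  d <- ncol(dy)
  G <- rep(g, each = nrow(dy))
  dxhat <- dy * G
  dvar <- rowSums(dxhat * cache$xc) * (-0.5) / (cache$sd^3)
  dmu <- -rowSums(dxhat) / cache$sd + dvar * (-2) * rowMeans(cache$xc)
  dx <- dxhat / cache$sd + cache$xc * (2 * dvar / d) + dmu / d
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

row_softmax <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

# forward pass over one chunk of unit ids/shapes (sentinels included);
# returns probs (T x 2, NAME then NON_NAME) and, if keep, the cache
tiny_forward <- function(p, cfg, ids, shapes, keep = FALSE) {
  T_ <- length(ids)
  d <- cfg$hidden_size
  X <- p$emb[ids, , drop = FALSE] + p$shape[shapes, , drop = FALSE] +
    p$pos[seq_len(T_), , drop = FALSE]
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  S <- (Q %*% t(K)) / sqrt(d)
  A <- row_softmax(S)
  H <- A %*% V
  O <- H %*% p$Wo
  ln1 <- layernorm_fwd(X + O, p$ln1_g, p$ln1_b)
  F1 <- ln1$y %*% p$Wf1 + rep(p$bf1, each = T_)
  F1r <- pmax(F1, 0)
  F2 <- F1r %*% p$Wf2 + rep(p$bf2, each = T_)
  ln2 <- layernorm_fwd(ln1$y + F2, p$ln2_g, p$ln2_b)
  logits <- cfg$feature_scale * (ln2$y %*% p$Wc) + rep(p$bc, each = T_)
  probs <- row_softmax(logits)
  out <- list(probs = probs)
  if (keep)
    out <- c(out, list(X = X, Q = Q, K = K, V = V, A = A, H = H,
                       ln1 = ln1, F1r = F1r, ln2 = ln2))
  out
}

# backward pass; labels: 1 = NAME, 2 = NON_NAME, NA = masked (sentinels)
tiny_backward <- function(p, cfg, ids, shapes, cache, labels) {
  T_ <- length(ids)
  d <- cfg$hidden_size
  active <- which(!is.na(labels))
  n_act <- length(active)
  dlogits <- cache$probs
  dlogits[cbind(active, labels[active])] <-
    dlogits[cbind(active, labels[active])] - 1
  dlogits[setdiff(seq_len(T_), active), ] <- 0
  dlogits <- dlogits / max(n_act, 1L)
  loss <- -sum(log(pmax(cache$probs[cbind(active, labels[active])], 1e-12))) /
    max(n_act, 1L)

  g <- list()
  g$Wc <- cfg$feature_scale * (t(cache$ln2$y) %*% dlogits)
  g$bc <- colSums(dlogits)
  dN2 <- cfg$feature_scale * (dlogits %*% t(p$Wc))
  b2 <- layernorm_bwd(dN2, cache$ln2, p$ln2_g)
  g$ln2_g <- b2$dg; g$ln2_b <- b2$db
  dZ2 <- b2$dx                       # flows to ln1$y (residual) and F2
  g$Wf2 <- t(cache$F1r) %*% dZ2
  g$bf2 <- colSums(dZ2)
  dF1 <- (dZ2 %*% t(p$Wf2)) * (cache$F1r > 0)
  g$Wf1 <- t(cache$ln1$y) %*% dF1
  g$bf1 <- colSums(dF1)
  dN1 <- dZ2 + dF1 %*% t(p$Wf1)
  b1 <- layernorm_bwd(dN1, cache$ln1, p$ln1_g)
  g$ln1_g <- b1$dg; g$ln1_b <- b1$db
  dZ1 <- b1$dx                       # flows to X (residual) and O
  g$Wo <- t(cache$H) %*% dZ1
  dH <- dZ1 %*% t(p$Wo)
  dA <- dH %*% t(cache$V)
  dV <- t(cache$A) %*% dH
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dQ <- (dS %*% cache$K) / sqrt(d)
  dK <- (t(dS) %*% cache$Q) / sqrt(d)
  g$Wq <- t(cache$X) %*% dQ
  g$Wk <- t(cache$X) %*% dK
  g$Wv <- t(cache$X) %*% dV
  dX <- dZ1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)

  g$emb <- matrix(0, nrow(p$emb), d)
  acc <- rowsum(dX, group = ids)
  g$emb[as.integer(rownames(acc)), ] <- acc
  g$shape <- matrix(0, 17L, d)
  accs <- rowsum(dX, group = shapes)
  g$shape[as.integer(rownames(accs)), ] <- accs
  g$pos <- matrix(0, nrow(p$pos), d)
  g$pos[seq_len(T_), ] <- dX
  list(loss = loss, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- classifier interface --------------------------------------------------

#' Initialize an untrained classifier backend
#'
#' Deterministic given `config$seed`. `train()` with `epochs = 0` returns
#' exactly this object.
#'
#' @param config A [model_config()].
#' @return A list of class `redact_classifier`.
#' @export
init_classifier <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (config$backend == "pretrained_uncased_transformer")
    stop("no pretrained transformer weights ship with this package; ",
         "use backend = 'tiny_test_transformer' or load a saved classifier",
         call. = FALSE)
  structure(list(config = config, params = init_params(config)),
            class = "redact_classifier")
}

#' @export
print.redact_classifier <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<redact_classifier: %s, %d parameters, threshold %.2f>\n",
              x$config$backend, n_par, x$config$non_name_threshold))
  invisible(x)
}

# turn one annotated narrative into training chunks:
# list of list(ids, shapes, labels) with sentinels added and masked
narrative_chunks <- function(nar, cfg, with_labels = TRUE) {
  toks <- tokenize(nar$text)
  if (nrow(toks) == 0L) return(list())
  enc <- encode_words(toks$text, cfg$vocab_size)
  word_labels <- if (with_labels) {
    ifelse(project_gold(toks, nar$spans) == "NAME", 1L, 2L)
  } else rep(NA_integer_, nrow(toks))
  capacity <- cfg$max_sequence_length - 2L
  sizes <- lengths(enc$ids)
  if (any(sizes > capacity)) {
    warning(sprintf(
      "%d word(s) exceed the chunk capacity of %d units; tail subwords truncated",
      sum(sizes > capacity), capacity))
    enc$ids[sizes > capacity] <-
      lapply(enc$ids[sizes > capacity], function(g) g[seq_len(capacity)])
    sizes <- lengths(enc$ids)
  }
  lapply(chunk_group_indices(sizes, capacity), function(ix) {
    ids <- c(1L, unlist(enc$ids[ix], use.names = FALSE), 2L)
    shapes <- c(1L, rep(enc$shapes[ix], sizes[ix]), 1L)
    labels <- c(NA_integer_, rep(word_labels[ix], sizes[ix]), NA_integer_)
    words <- rep(ix, sizes[ix])
    list(ids = ids, shapes = shapes, labels = labels, words = words)
  })
}

#' Fine-tune the token classifier
#'
#' Trains the backend on token labels projected from the corpus's gold NAME
#' spans, with categorical cross-entropy over the two classes and the Adam
#' optimizer, one chunk per update step. Fully reproducible given
#' `config$seed` (initialization and epoch shuffling both derive from it).
#'
#' @param corpus Non-empty list of [annotated_narrative()] objects.
#' @param config A [model_config()].
#' @param quiet Suppress the per-epoch loss log.
#' @return A `redact_classifier`. The per-epoch mean losses are attached as
#'   attribute `epoch_loss`.
#' @export
train <- function(corpus, config = model_config(), quiet = FALSE) {
  stopifnot(length(corpus) > 0L)
  clf <- init_classifier(config)
  if (config$epochs == 0L) return(clf)
  chunks <- unlist(lapply(corpus, narrative_chunks, cfg = config),
                   recursive = FALSE)
  chunks <- Filter(function(ch) any(!is.na(ch$labels)), chunks)
  if (length(chunks) == 0L) stop("corpus contains no tokenizable text")
  all_labels <- unlist(lapply(chunks, `[[`, "labels"))
  if (length(unique(stats::na.omit(all_labels))) < 2L)
    warning("degenerate training corpus: only one token class present")
  set.seed(config$seed + 1L)
  params <- clf$params
  state <- adam_init(params)
  epoch_loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(chunks))
    losses <- numeric(length(chunks))
    for (j in seq_along(ord)) {
      ch <- chunks[[ord[j]]]
      fw <- tiny_forward(params, config, ch$ids, ch$shapes, keep = TRUE)
      bk <- tiny_backward(params, config, ch$ids, ch$shapes, fw, ch$labels)
      upd <- adam_step(params, bk$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      losses[j] <- bk$loss
    }
    epoch_loss[ep] <- mean(losses)
    stopifnot(is.finite(epoch_loss[ep]))
    if (!quiet)
      message(sprintf("epoch %d/%d: mean loss %.5f", ep, config$epochs,
                      epoch_loss[ep]))
  }
  clf$params <- params
  attr(clf, "epoch_loss") <- epoch_loss
  clf
}

#' Per-token NAME/NON-NAME probabilities
#'
#' Runs the classifier over a narrative, chunking long inputs, and aligns
#' subword scores back to alphanumeric tokens. A token's NON-NAME
#' probability is the minimum over its subword units — a token counts as a
#' name if any of its pieces looks like one, the privacy-conservative
#' aggregation.
#'
#' @param text Narrative text.
#' @param classifier A `redact_classifier`.
#' @return Data.frame with columns `token`, `start`, `end`, `p_name`,
#'   `p_non_name`, one row per token of `tokenize(text)`.
#' @export
predict_scores <- function(text, classifier) {
  stopifnot(inherits(classifier, "redact_classifier"))
  cfg <- classifier$config
  toks <- tokenize(text)
  if (nrow(toks) == 0L)
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), p_name = numeric(0),
                      p_non_name = numeric(0)))
  chunks <- narrative_chunks(list(text = text, spans = NULL), cfg,
                             with_labels = FALSE)
  p_nn <- rep(NA_real_, nrow(toks))
  for (ch in chunks) {
    fw <- tiny_forward(classifier$params, cfg, ch$ids, ch$shapes)
    inner <- fw$probs[c(-1L, -length(ch$ids)), , drop = FALSE]
    agg <- tapply(inner[, 2L], ch$words, min)
    idx <- as.integer(names(agg))
    p_nn[idx] <- pmin(p_nn[idx], agg, na.rm = TRUE)
  }
  stopifnot(!anyNA(p_nn))
  data.frame(token = toks$text, start = toks$start, end = toks$end,
             p_name = 1 - p_nn, p_non_name = p_nn,
             stringsAsFactors = FALSE)
}

#' Predict token labels with the threshold decision rule
#'
#' A token is labelled `NON_NAME` only when its NON-NAME probability
#' strictly exceeds the configured threshold; otherwise `NAME`. With the
#' default threshold of 0.9 the model must be confident to leave a token
#' unredacted.
#'
#' @inheritParams predict_scores
#' @param threshold Optional override of the classifier's configured
#'   `non_name_threshold`.
#' @return Character label vector aligned with `tokenize(text)`.
#' @export
predict_tokens <- function(text, classifier, threshold = NULL) {
  thr <- if (is.null(threshold)) classifier$config$non_name_threshold
         else threshold
  stopifnot(thr > 0, thr <= 1)
  sc <- predict_scores(text, classifier)
  ifelse(sc$p_non_name > thr, "NON_NAME", "NAME")
}

#' Merge consecutive NAME tokens into spans
#'
#' Maximal runs of NAME-labelled tokens become one span from the first
#' token's start to the last token's end, covering intervening
#' non-alphanumeric characters (so "Hanna Rosling" redacts as one unit).
#'
#' @param tokens Token data.frame from [tokenize()].
#' @param labels Character label vector of equal length.
#' @return Span data.frame.
#' @export
labels_to_spans <- function(tokens, labels) {
  if (nrow(tokens) != length(labels))
    stop("tokens and labels differ in length", call. = FALSE)
  is_name <- labels == "NAME"
  if (!any(is_name)) return(empty_spans())
  r <- rle(is_name)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  data.frame(start = tokens$start[starts_i[keep]],
             end = tokens$end[ends_i[keep]],
             label = "NAME", subtype = "unspecified",
             stringsAsFactors = FALSE)
}

#' Save / load a classifier directory
#'
#' The classifier is stored as a directory holding a `config.json` manifest
#' (keys mirror [model_config()] fields) and a `weights.json` file with full
#' numeric precision.
#'
#' @param classifier A `redact_classifier`.
#' @param path Directory path.
#' @return `path` / the restored classifier.
#' @export
save_classifier <- function(classifier, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(classifier$config),
                       file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(classifier$params, file.path(path, "weights.json"),
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  cfg <- jsonlite::read_json(file.path(path, "config.json"),
                             simplifyVector = TRUE)
  config <- model_config(cfg$epochs, cfg$learning_rate,
                         cfg$non_name_threshold, cfg$max_sequence_length,
                         cfg$seed, cfg$backend, cfg$hidden_size,
                         cfg$vocab_size, cfg$feature_scale)
  w <- jsonlite::read_json(file.path(path, "weights.json"),
                           simplifyVector = TRUE)
  params <- lapply(w, function(x) if (is.matrix(x)) x else as.numeric(x))
  structure(list(config = config, params = params),
            class = "redact_classifier")
}
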