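#' Build one striatal hemisphere
#'
#' Places 40 D1- and 40 D2-MSNs in each channel of the grid and connects
#' every ordered neuron pair independently with the probability given by the
#' connectivity kernel for the pair's type and spatial category. No
#' self-connections, no multapses. Weights are the type-pair conductance
#' magnitudes, delays the category delays.
#'
#' @param grid A [channel_grid()].
#' @param kernel A [connectivity_kernel()].
#' @param params Named list with elements `D1` and `D2`, each a
#'   [msn_parameters()] object.
#' @param background A [background_input()] data.frame.
#' @param n_per_type Neurons of each type per channel (default 40).
#' @param hemisphere `"L"` or `"R"` label for the roster.
#' @param seed Integer seed; the construction is deterministic given the seed.
#' @return An object of class `striatal_network` with elements `neurons`
#'   (data.frame: id, hemisphere, type, row, col, channel), `synapses`
#'   (data.frame: pre, post, weight_nS, delay_ms, category), `grid`,
#'   `kernel`, `params`, `background`.
#' @export
build_hemisphere <- function(grid = channel_grid(),
                             kernel = connectivity_kernel(),
                             params = list(D1 = msn_parameters("D1"),
                                           D2 = msn_parameters("D2")),
                             background = background_input(),
                             n_per_type = 40L,
                             hemisphere = "L",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ch <- n_channels(grid)
  n_per_type <- as.integer(n_per_type)
  co <- channel_coords(seq_len(n_ch), grid)
  neurons <- data.frame(
    id = seq_len(n_ch * 2L * n_per_type),
    hemisphere = hemisphere,
    type = rep(rep(c("D1", "D2"), each = n_per_type), times = n_ch),
    row = rep(co[, 1], each = 2L * n_per_type),
    col = rep(co[, 2], each = 2L * n_per_type),
    channel = rep(seq_len(n_ch), each = 2L * n_per_type),
    stringsAsFactors = FALSE
  )

  catm <- channel_category_matrix(grid, diagonal = kernel$diagonal)
  kvec <- unname(kernel$k)
  dvec <- unname(kernel$delays)

  syn <- vector("list", 4L)
  i <- 0L
  for (pre_t in c("D1", "D2")) {
    pre_ids <- neurons$id[neurons$type == pre_t]
    pre_ch <- neurons$channel[pre_ids]
    for (post_t in c("D1", "D2")) {
      post_ids <- neurons$id[neurons$type == post_t]
      post_ch <- neurons$channel[post_ids]
      cm <- catm[pre_ch, post_ch, drop = FALSE]
      p <- kernel$rho[pre_t, post_t] * kvec[cm]
      if (any(p > 1)) {
        warning("scaled connection probability exceeded 1 and was clipped")
        p <- pmin(p, 1)
      }
      hit <- matrix(stats::runif(length(p)) < p, nrow = length(pre_ids))
      if (pre_t == post_t) diag(hit) <- FALSE  # no autapses
      idx <- which(hit, arr.ind = TRUE, useNames = FALSE)
      cat_i <- cm[idx]
      i <- i + 1L
      syn[[i]] <- data.frame(
        pre = pre_ids[idx[, 1]],
        post = post_ids[idx[, 2]],
        weight_nS = kernel$J[pre_t, post_t],
        delay_ms = dvec[cat_i],
        category = c("within", "near", "far")[cat_i],
        stringsAsFactors = FALSE
      )
    }
  }
  synapses <- do.call(rbind, syn)
  synapses <- synapses[order(synapses$pre, synapses$post), , drop = FALSE]
  rownames(synapses) <- NULL

  structure(
    list(neurons = neurons, synapses = synapses, grid = grid,
         kernel = kernel, params = params, background = background,
         n_per_type = n_per_type),
    class = "striatal_network"
  )
}

#' Build the full two-hemisphere network
#'
#' The two hemispheres are built independently from separate seed streams
#' derived from `seed`; there are no inter-hemispheric synapses at the level
#' of the striatum.
#'
#' @inheritParams build_hemisphere
#' @param seed Integer master seed.
#' @return A `striatal_network` containing both hemispheres.
#' @export
build_network <- function(grid = channel_grid(),
                          kernel = connectivity_kernel(),
                          params = list(D1 = msn_parameters("D1"),
                                        D2 = msn_parameters("D2")),
                          background = background_input(),
                          n_per_type = 40L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  L <- build_hemisphere(grid, kernel, params, background, n_per_type,
                        hemisphere = "L", seed = sub[1])
  R <- build_hemisphere(grid, kernel, params, background, n_per_type,
                        hemisphere = "R", seed = sub[2])
  off <- nrow(L$neurons)
  R$neurons$id <- R$neurons$id + off
  R$synapses$pre <- R$synapses$pre + off
  R$synapses$post <- R$synapses$post + off
  net <- L
  net$neurons <- rbind(L$neurons, R$neurons)
  net$synapses <- rbind(L$synapses, R$synapses)
  rownames(net$neurons) <- rownames(net$synapses) <- NULL
  net
}

#' @export
print.striatal_network <- function(x, ...) {
  cat(sprintf("<striatal_network> %d neurons (%s), %d synapses, kernel=%s\n",
              nrow(x$neurons),
              paste(unique(x$neurons$hemisphere), collapse = "+"),
              nrow(x$synapses), x$kernel$mode))
  invisible(x)
}

#' Sever connections of a type pair between two channels
#'
#' Sets the conductance of all synapses of the given (pre, post) type pair
#' whose pre- and postsynaptic neurons lie in *different* members of the
#' channel pair to zero (both directions, in every hemisphere present).
#' Within-channel synapses are untouched. Idempotent.
#'
#' @param net A `striatal_network`.
#' @param pre_type,post_type MSN types of the synapses to sever.
#' @param channels Length-2 integer vector of channel indices.
#' @return The modified network.
#' @export
sever_connections <- function(net, pre_type = "D2", post_type = "D2",
                              channels) {
  stopifnot(length(channels) == 2)
  if (!all(channels %in% net$neurons$channel)) stop("channel does not exist")
  ch_of <- net$neurons$channel
  hem_of <- net$neurons$hemisphere
  ty_of <- net$neurons$type
  s <- net$synapses
  cross <- (ch_of[s$pre] == channels[1] & ch_of[s$post] == channels[2]) |
           (ch_of[s$pre] == channels[2] & ch_of[s$post] == channels[1])
  sel <- cross &
    ty_of[s$pre] == pre_type & ty_of[s$post] == post_type &
    hem_of[s$pre] == hem_of[s$post]
  if (!any(sel & s$weight_nS > 0))
    warning("no nonzero synapses matched the severing selection")
  net$synapses$weight_nS[sel] <- 0
  net
}

#' Realized connection fractions by type pair and spatial category
#'
#' Counts synapses per (pre type, post type, category) and divides by the
#' number of candidate ordered pairs in that stratum; used to check the
#' construction against the kernel probabilities.
#'
#' @param net A single-hemisphere `striatal_network`.
#' @return data.frame with columns `pre_type`, `post_type`, `category`,
#'   `n_pairs`, `n_syn`, `fraction`, `target`.
#' @export
connection_fractions <- function(net) {
  stopifnot(length(unique(net$neurons$hemisphere)) == 1)
  grid <- net$grid
  n_ch <- n_channels(grid)
  catm <- channel_category_matrix(grid, diagonal = net$kernel$diagonal)
  n_near <- sum(catm[1, ] == 2L)
  npt <- net$n_per_type
  res <- expand.grid(pre_type = c("D1", "D2"), post_type = c("D1", "D2"),
                     category = c("within", "near", "far"),
                     stringsAsFactors = FALSE)
  ty_of <- net$neurons$type
  s <- net$synapses
  for (r in seq_len(nrow(res))) {
    same <- res$pre_type[r] == res$post_type[r]
    n_pairs <- switch(res$category[r],
      within = n_ch * npt * (npt - if (same) 1L else 0L),
      near = n_ch * n_near * npt * npt,
      far = n_ch * (n_ch - 1L - n_near) * npt * npt)
    n_syn <- sum(ty_of[s$pre] == res$pre_type[r] &
                 ty_of[s$post] == res$post_type[r] &
                 s$category == res$category[r])
    res$n_pairs[r] <- n_pairs
    res$n_syn[r] <- n_syn
    res$fraction[r] <- n_syn / n_pairs
    res$target[r] <- scaled_probability(res$pre_type[r], res$post_type[r],
                                        res$category[r], net$kernel)
  }
  res
}

#' Write / read a network as CSV tables
#'
#' `neurons.csv` holds (id, hemisphere, type, row, col, channel);
#' `synapses.csv` holds (pre, post, weight_nS, delay_ms, category).
#'
#' @param net A `striatal_network`.
#' @param dir Output directory (created if needed).
#' @return `write_network` returns the directory invisibly; `read_network`
#'   returns a list with the two data.frames.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(net$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  utils::write.csv(net$synapses, file.path(dir, "synapses.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  list(
    neurons = utils::read.csv(file.path(dir, "neurons.csv"),
                              stringsAsFactors = FALSE),
    synapses = utils::read.csv(file.path(dir, "synapses.csv"),
                               stringsAsFactors = FALSE)
  )
}
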