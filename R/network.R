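#' Default hippocampal architecture
#'
#' Returns the configuration list describing the standard circuit: an
#' external `Input` layer clamped to the stimulus, superficial and deep
#' entorhinal layers (`EC_in`, `EC_out`), and the three hidden subfields
#' `DG` (400 units), `CA3` (80 units) and `CA1` (100 units).  The
#' trisynaptic pathway (TSP) runs EC_in -> DG -> CA3 -> CA1 with sparse
#' connectivity (DG and CA3 each sample 25% of EC_in; CA3 samples 5% of
#' DG) and a fast learning rate; the monosynaptic pathway (MSP) is the
#' full EC_in -> CA1 projection with a 10x slower learning rate.  CA3
#' carries a full off-diagonal recurrent projection and CA1 is linked
#' bidirectionally with EC_out.
#'
#' The canonical configuration is stored as a YAML file at
#' `system.file("extdata", "hippocampus.yaml", package = "hippcat")`;
#' this function loads it and applies task-dependent overrides.
#'
#' @param input_size number of Input/EC_in/EC_out units (task dependent).
#' @param ec_k set-point inhibition target (number of strongly active
#'   units) for the EC layers; conventionally the number of active units
#'   in a training pattern.
#' @param msp_lr learning rate of monosynaptic-pathway projections
#'   (including CA1 <-> EC_out).  Default 0.002; the typicality task uses
#'   a smaller value because of its highly overlapping exemplars.
#' @param tsp_lr learning rate of trisynaptic-pathway projections.
#' @param overrides named list merged into the configuration (e.g.
#'   `list(layers = list(CA1 = list(gain = 20)))`).
#' @return a configuration list with elements `layers` and `projections`.
#' @export
default_architecture <- function(input_size, ec_k,
                                 msp_lr = 0.002, tsp_lr = 0.02,
                                 overrides = NULL) {
  path <- system.file("extdata", "hippocampus.yaml", package = "hippcat")
  cfg <- read_architecture(path)
  for (nm in c("Input", "EC_in", "EC_out")) {
    cfg$layers[[nm]]$size <- input_size
    if (nm != "Input") cfg$layers[[nm]]$k <- ec_k
  }
  cfg$layers$Input$k <- ec_k
  for (i in seq_along(cfg$projections)) {
    p <- cfg$projections[[i]]
    if (isTRUE(p$learnable) && !isTRUE(p$lr_fixed)) {
      cfg$projections[[i]]$lr <- switch(p$pathway,
        TSP = tsp_lr, MSP = msp_lr,
        stop("learnable projection must be tagged TSP or MSP"))
    }
  }
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

#' Read / write an architecture configuration
#'
#' Architecture configurations are plain YAML files with a `layers` table
#' (name, size, k, gain) and a `projections` table (src, dst, type,
#' frac, learnable, pathway, strength, gates, init range).
#'
#' @param path file path.
#' @return `read_architecture()` returns the configuration list;
#'   `write_architecture()` returns `path` invisibly.
#' @export
read_architecture <- function(path) {
  cfg <- yaml::read_yaml(path)
  names(cfg$layers) <- vapply(cfg$layers, `[[`, "", "name")
  names(cfg$projections) <- vapply(cfg$projections, function(p)
    paste0(p$src, "->", p$dst), "")
  cfg
}

#' @rdname read_architecture
#' @param config configuration list.
#' @export
write_architecture <- function(config, path) {
  names(config$layers) <- NULL
  names(config$projections) <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

proj_key <- function(src, dst) paste0(src, "->", dst)

#' Weight contrast enhancement
#'
#' Learnable weights are stored in \[0, 1\] and mapped through a
#' sigmoidal contrast function before entering the net input:
#' `w_eff = 1 / (1 + (off * (1 - w) / w)^gain)`.  The slope near the
#' midpoint is of order `gain`, so small learned deviations are
#' amplified; an offset `off > 1` shifts the sigmoid so that mid-range
#' (untrained) weights are suppressed while learned increases break
#' through — enhancing the contrast between trained structure and the
#' random initialization.  `gain = 1, off = 1` is the identity; fixed
#' projections use their weights directly.
#'
#' @param w stored weight matrix or vector (values in \[0, 1\]).
#' @param gain contrast gain (default 6).
#' @param off contrast offset (default 1).
#' @return effective weights, same shape as `w`.
#' @export
weight_contrast <- function(w, gain = 6, off = 1) {
  if (gain == 1 && off == 1) return(w)
  out <- w
  mid <- w > 0 & w < 1
  out[mid] <- 1 / (1 + (off * (1 - w[mid]) / w[mid])^gain)
  out
}

# Inverse of weight_contrast: stored weight giving effective weight e.
weight_contrast_inv <- function(e, gain = 6, off = 1) {
  out <- e
  mid <- e > 0 & e < 1
  r <- ((1 - e[mid]) / e[mid])^(1 / gain) / off
  out[mid] <- 1 / (1 + r)
  out
}

#' Build a hippocampal network
#'
#' Instantiates the circuit described by a configuration: builds binary
#' connectivity masks (each destination unit samples
#' `round(frac * src_size)` distinct source units, minimum 1) and draws
#' initial weights uniformly from the projection's init range.  Both the
#' mask topology and the weight values are functions of `seed` alone, so
#' identical calls reproduce the network bit-exactly.
#'
#' @param config configuration list from [default_architecture()] or
#'   [read_architecture()].
#' @param seed non-negative integer; the network's random initialization.
#' @return an object of class `hnet`.
#' @export
build_network <- function(config, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  layer_names <- names(config$layers)
  for (lay in config$layers) {
    if (lay$size <= 0) stop("layer size must be positive: ", lay$name)
    if (lay$k < 1 || lay$k > lay$size)
      stop("k_active must be in [1, size] for layer ", lay$name)
  }
  set.seed(as.integer(seed))
  projections <- list()
  for (p in config$projections) {
    if (!p$src %in% layer_names) stop("unknown source layer: ", p$src)
    if (!p$dst %in% layer_names) stop("unknown destination layer: ", p$dst)
    ns <- config$layers[[p$src]]$size
    nd <- config$layers[[p$dst]]$size
    type <- p$type
    if (type == "one_to_one") {
      if (ns != nd)
        stop("one-to-one projection between layers of unequal size: ",
             proj_key(p$src, p$dst))
      mask <- diag(1, nd, ns)
      W <- diag(if (is.null(p$weight)) 1 else p$weight, nd, ns)
      fanin <- 1
    } else if (type == "full") {
      mask <- matrix(1, nd, ns)
      fanin <- ns
    } else if (type == "recurrent") {
      mask <- matrix(1, nd, ns) - diag(1, nd, ns)
      fanin <- ns - 1
    } else if (type == "sparse") {
      frac <- p$frac
      if (is.null(frac) || frac <= 0 || frac > 1)
        stop("connectivity fraction outside (0, 1]: ",
             proj_key(p$src, p$dst))
      fanin <- max(1L, as.integer(round(frac * ns)))
      mask <- matrix(0, nd, ns)
      for (i in seq_len(nd)) mask[i, sample.int(ns, fanin)] <- 1
    } else stop("unknown projection type: ", type)
    learnable <- isTRUE(p$learnable)
    wc_gain <- if (!is.null(p$wc_gain)) p$wc_gain
               else if (learnable) 6 else 1
    wc_off <- if (!is.null(p$wc_off)) p$wc_off else 1
    if (learnable) {
      # stored-space init: a narrow mid-range band keeps initial effective
      # weights below the contrast-expression threshold (see vignette)
      init <- if (is.null(p$init)) c(0.45, 0.55) else p$init
      W <- matrix(runif(nd * ns, init[1], init[2]), nd, ns) * mask
      We <- weight_contrast(W, wc_gain, wc_off) * mask
    } else if (type != "one_to_one") {
      W <- mask * (if (is.null(p$weight)) 1 else p$weight)
      We <- W
    } else {
      We <- W
    }
    k_src <- config$layers[[p$src]]$k
    norm <- if (type == "one_to_one") 1 else max(1, fanin * k_src / ns)
    gates <- lapply(stats::setNames(PHASES, PHASES), function(ph) {
      g <- p$gates[[ph]]
      if (is.null(g)) 1 else g
    })
    projections[[proj_key(p$src, p$dst)]] <- list(
      src = p$src, dst = p$dst, type = type,
      W = W, We = We, wc_gain = wc_gain, wc_off = wc_off,
      mask = mask, fanin = fanin, norm = norm,
      strength = if (is.null(p$strength)) 1 else p$strength,
      learnable = learnable,
      lr = if (learnable) p$lr else 0,
      hebb = if (is.null(p$hebb)) 0 else p$hebb,
      pathway = if (is.null(p$pathway)) "fixed" else p$pathway,
      gates = gates)
  }
  structure(list(
    layers = config$layers,
    projections = projections,
    seed = as.integer(seed),
    condition = "intact",
    config = config), class = "hnet")
}

#' @export
print.hnet <- function(x, ...) {
  sizes <- vapply(x$layers, `[[`, 0, "size")
  cat("<hnet> hippocampal network (seed ", x$seed, ", ",
      x$condition, ")\n", sep = "")
  cat("  layers:", paste0(names(sizes), "[", sizes, "]", collapse = " "), "\n")
  cat("  projections:", paste(names(x$projections), collapse = ", "), "\n")
  invisible(x)
}

# Effective gate (phase gate x lesion/strength scalar) of a projection.
proj_gate <- function(p, phase, gate_override = NULL, key = NULL) {
  g <- p$gates[[phase]]
  if (is.null(g)) g <- 1
  if (!is.null(gate_override) && !is.null(key) && key %in% names(gate_override))
    g <- gate_override[[key]]
  g * p$strength
}

#' Excitatory drive of a layer
#'
#' Computes, for every unit of `dst_layer`, the phase-gated weighted sum
#' of presynaptic activity across all incoming projections.  Each
#' projection's weighted sum is normalized by its expected active fan-in
#' (`max(1, fanin * k_src / n_src)`; 1 for one-to-one links) so that
#' drives are comparable between sparse and full projections, then
#' scaled by the projection's fixed strength and its gate for `phase`.
#'
#' @param dst_layer layer name.
#' @param network an `hnet`.
#' @param state named list of activation vectors (one per source layer).
#' @param phase phase label (one of `"trough"`, `"peak"`, `"plus"`,
#'   `"minus"`, `"test"`).
#' @param gate_override optional named list (by `"src->dst"` key) of gate
#'   values replacing the phase gate, e.g. `list("EC_out->EC_in" = 0)`.
#' @return numeric vector of net inputs for `dst_layer`.
#' @export
net_input <- function(dst_layer, network, state, phase = "test",
                      gate_override = NULL) {
  drive <- numeric(network$layers[[dst_layer]]$size)
  for (key in names(network$projections)) {
    p <- network$projections[[key]]
    if (p$dst != dst_layer) next
    g <- proj_gate(p, phase, gate_override, key)
    if (g == 0) next
    a <- state[[p$src]]
    if (is.null(a)) stop("missing activations for source layer ", p$src)
    drive <- drive + (g / p$norm) * as.numeric(p$We %*% a)
  }
  drive
}

#' k-winner-take-all activation
#'
#' Set-point inhibition: the layer-wide inhibition level is placed at the
#' midpoint between the k-th and (k+1)-th largest drives, and each unit's
#' activation is a logistic function of (drive - inhibition) with slope
#' `gain`.  Approximately `k` units end up strongly active (above 0.5);
#' the transfer is monotone in drive and equivariant under permutation,
#' and ties produce identical activations.
#'
#' @param drives finite numeric vector of net inputs.
#' @param k_active target number of strongly active units.
#' @param gain logistic slope of the transfer function.
#' @param floor lower bound on the inhibition level (leak): units whose
#'   drive does not exceed `floor` stay weakly active even when fewer
#'   than `k_active` units are strongly driven.  Default `-Inf` (pure
#'   set-point inhibition).
#' @return activation vector in (0, 1).
#' @export
apply_kwta <- function(drives, k_active, gain, floor = -Inf) {
  if (any(!is.finite(drives))) stop("non-finite drives")
  n <- length(drives)
  stopifnot(k_active >= 1, k_active <= n)
  ds <- sort(drives, decreasing = TRUE)
  theta <- if (k_active < n) (ds[k_active] + ds[k_active + 1]) / 2
           else ds[n] - 1 / gain
  theta <- max(theta, floor)
  1 / (1 + exp(-gain * (drives - theta)))
}

#' Settle the network to a fixed point
#'
#' Iterates net-input + k-winner-take-all updates over the unclamped
#' layers (a deterministic sweep in the anatomical order EC_in, DG, CA3,
#' CA1, EC_out, each layer seeing activity already updated this cycle)
#' until the maximum absolute activation change falls below `tol` or
#' `max_cycles` is reached.  Clamped layers hold their values exactly.
#' Non-convergence is not an error: the returned state carries
#' `converged = FALSE`.
#'
#' @param network an `hnet`.
#' @param clamps named list of activation vectors to clamp (the stimulus
#'   is clamped on `Input`; the target on `EC_out` in the plus phase).
#' @param phase phase label determining projection gates.
#' @param max_cycles settle cycle budget (default 100).
#' @param tol convergence tolerance on activations (default 1e-4).
#' @param gate_override see [net_input()].
#' @param step integration step: each cycle moves a layer's activation
#'   this fraction of the way towards its instantaneous k-winner-take-all
#'   target.  Values below 1 damp the winner-flipping oscillations that
#'   discrete k-WTA updates can produce.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation; identical results).
#' @return list with `act` (named list of activation vectors), `cycles`,
#'   `converged`, and `phase`.
#' @export
settle <- function(network, clamps, phase = "test", max_cycles = 100,
                   tol = 1e-4, gate_override = NULL, step = 0.3,
                   engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  lnames <- names(network$layers)
  sizes <- vapply(network$layers, `[[`, 0, "size")
  for (nm in names(clamps)) {
    if (!nm %in% lnames) stop("clamp on unknown layer ", nm)
    if (length(clamps[[nm]]) != sizes[[nm]])
      stop("clamp length mismatch for layer ", nm)
  }
  act <- lapply(network$layers, function(l) numeric(l$size))
  for (nm in names(clamps)) act[[nm]] <- as.numeric(clamps[[nm]])
  free <- intersect(LAYER_ORDER, setdiff(lnames, names(clamps)))

  if (engine == "R") {
    cycles <- 0L; converged <- FALSE
    while (cycles < max_cycles) {
      cycles <- cycles + 1L
      delta <- 0
      for (nm in free) {
        l <- network$layers[[nm]]
        d <- net_input(nm, network, act, phase, gate_override)
        target <- apply_kwta(d, l$k, l$gain,
                             if (is.null(l$floor)) 0 else l$floor)
        new <- act[[nm]] + step * (target - act[[nm]])
        delta <- max(delta, max(abs(new - act[[nm]])))
        act[[nm]] <- new
      }
      if (delta < tol) { converged <- TRUE; break }
    }
    return(list(act = act, cycles = cycles, converged = converged,
                phase = phase))
  }

  # compiled path: flatten projections targeting free layers
  idx <- stats::setNames(seq_along(lnames) - 1L, lnames)
  Ws <- list(); srcs <- integer(); dsts <- integer(); coefs <- numeric()
  for (key in names(network$projections)) {
    p <- network$projections[[key]]
    if (!p$dst %in% free) next
    g <- proj_gate(p, phase, gate_override, key)
    if (g == 0) next
    Ws[[length(Ws) + 1L]] <- p$We
    srcs <- c(srcs, idx[[p$src]])
    dsts <- c(dsts, idx[[p$dst]])
    coefs <- c(coefs, g / p$norm)
  }
  res <- settle_core(act, Ws, srcs, dsts, coefs,
                     match(free, lnames) - 1L,
                     vapply(network$layers, `[[`, 0, "k"),
                     vapply(network$layers, `[[`, 0, "gain"),
                     vapply(network$layers, function(l)
                       if (is.null(l$floor)) 0 else l$floor, 0),
                     as.integer(max_cycles), tol, step)
  act <- stats::setNames(res$act, lnames)
  list(act = act, cycles = res$cycles, converged = res$converged,
       phase = phase)
}
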