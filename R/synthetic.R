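# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration of the synthetic multilayer benchmark generator
#'
#' Each layer is grown by an extended preferential-attachment process: a new
#' node attaches with \code{m} edges to existing nodes proportionally to
#' their degree; after each attachment, with probability \code{p} one extra
#' edge is added between randomly chosen existing nodes, and with
#' probability \code{q} one existing edge is removed, chosen only among
#' edges whose removal isolates neither endpoint (no node may become
#' isolated). For \code{p = q = 0} the process is exactly the
#' Barabasi-Albert scale-free model; \code{p} and \code{q} emulate the
#' duplication and divergence mechanisms of biological networks. Layers get
#' disjoint node namespaces and are wired by uniformly sampled interlayer
#' edges until these make up \code{interlayerFraction} of all edges.
#'
#' @param n nodes per layer
#' @param m edges attached by each new node (\code{1 <= m < n})
#' @param p probability of the extra-edge event, in \[0, 1\]
#' @param q probability of the edge-removal event, in \[0, 1\]
#' @param numLayers number of intralayer graphs (the benchmark uses 2)
#' @param interlayerFraction fraction of the final edge total that is
#'   interlayer (the benchmark uses 0.20), in \[0, 1)
#' @param seed RNG seed for [generateMultilayer()]
#' @return a validated list of class \code{GeneratorConfig}
#' @export
generatorConfig <- function(n = 100, m = 2, p = 0.5, q = 0.4, numLayers = 2,
                            interlayerFraction = 0.20, seed = 1L) {
  stopifnot(n >= 2, m >= 1, numLayers >= 1,
            p >= 0, p <= 1, q >= 0, q <= 1)
  if (m >= n) stop("m must be smaller than n")
  if (interlayerFraction < 0 || interlayerFraction >= 1)
    stop("interlayerFraction must lie in [0, 1)")
  structure(list(n = as.integer(n), m = as.integer(m), p = p, q = q,
                 numLayers = as.integer(numLayers),
                 interlayerFraction = interlayerFraction,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Grow one extended preferential-attachment layer
#'
#' Uses the current RNG stream; callers wanting reproducibility seed it
#' (as [generateMultilayer()] does). Events per growth step are applied in
#' a fixed order: attachment, then the p-addition, then the q-removal.
#'
#' @param config a [generatorConfig()]
#' @param layerId integer layer tag for the produced edges
#' @param nodePrefix prefix making this layer's node namespace disjoint
#' @return data.frame of intralayer edges (u, v, layer)
#' @export
generateLayer <- function(config, layerId, nodePrefix = "") {
  n <- config$n; m <- config$m
  deg <- integer(n)
  eu <- integer(0); ev <- integer(0)           # canonical eu < ev
  has_edge <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(a, b) paste0(a, ".", b)
  add_edge <- function(a, b) {
    if (a > b) { t <- a; a <- b; b <- t }
    eu <<- c(eu, a); ev <<- c(ev, b)
    deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L
    assign(key(a, b), TRUE, envir = has_edge)
  }
  drop_edge <- function(i) {
    a <- eu[i]; b <- ev[i]
    rm(list = key(a, b), envir = has_edge)
    deg[a] <<- deg[a] - 1L; deg[b] <<- deg[b] - 1L
    eu <<- eu[-i]; ev <<- ev[-i]
  }
  exists_edge <- function(a, b) {
    if (a > b) { t <- a; a <- b; b <- t }
    exists(key(a, b), envir = has_edge)
  }
  for (t in (m + 1L):n) {
    existing <- seq_len(t - 1L)
    w <- deg[existing]
    targets <- if (all(w == 0L)) {
      sample(existing, min(m, length(existing)))
    } else {
      # preferential attachment: m distinct targets, degree-proportional
      sample(existing, min(m, length(existing)), prob = w + 1e-12)
    }
    for (tg in targets) add_edge(t, tg)
    if (config$p > 0 && stats::runif(1) < config$p) {
      for (try in 1:50) {
        pr <- sample(t, 2L)
        if (!exists_edge(pr[1], pr[2])) { add_edge(pr[1], pr[2]); break }
      }
    }
    if (config$q > 0 && stats::runif(1) < config$q) {
      removable <- which(deg[eu] >= 2L & deg[ev] >= 2L)
      if (length(removable))
        drop_edge(removable[sample.int(length(removable), 1L)])
    }
  }
  data.frame(u = paste0(nodePrefix, eu), v = paste0(nodePrefix, ev),
             layer = as.integer(layerId), stringsAsFactors = FALSE)
}

#' Generate a synthetic multilayer network with known ground truth
#'
#' Layers are tagged \code{1..numLayers}; interlayer edges get identifier
#' \code{numLayers + 1}. The interlayer edge count is chosen so that it
#' equals \code{interlayerFraction} of the final edge total:
#' \code{round(f / (1 - f) * |E_intra|)} edges between uniformly sampled
#' cross-layer node pairs (duplicates rejected). The ground-truth mapping of
#' a network to any of its noisy counterparts is the identity on node
#' identifiers.
#'
#' @param config a [generatorConfig()]
#' @return list with elements \code{network} (a
#'   [MultilayerNetwork-class]) and \code{mapping} (a two-column
#'   data.frame \code{source}, \code{target}; here the identity)
#' @examples
#' gen <- generateMultilayer(generatorConfig(n = 50, m = 2, p = 0, q = 0,
#'                                           seed = 7))
#' edgeCount(gen$network)
#' @export
generateMultilayer <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  .withSeed(config$seed, {
    layers <- lapply(seq_len(config$numLayers), function(k)
      generateLayer(config, layerId = k, nodePrefix = sprintf("L%d_", k)))
    intra <- do.call(rbind, layers)
    f <- config$interlayerFraction
    nInter <- if (f > 0) round(f / (1 - f) * nrow(intra)) else 0L
    interId <- config$numLayers + 1L
    inter <- NULL
    if (nInter > 0) {
      if (config$numLayers < 2L)
        stop("interlayer edges require at least two layers")
      nodesByLayer <- lapply(layers, function(e) unique(c(e$u, e$v)))
      seen <- character(0)
      iu <- character(nInter); iv <- character(nInter)
      got <- 0L
      while (got < nInter) {
        ab <- sample.int(config$numLayers, 2L)
        a <- sample(nodesByLayer[[ab[1]]], 1L)
        b <- sample(nodesByLayer[[ab[2]]], 1L)
        k <- paste(min(a, b), max(a, b))
        if (k %in% seen) next
        seen <- c(seen, k)
        got <- got + 1L
        iu[got] <- a; iv[got] <- b
      }
      inter <- data.frame(u = iu, v = iv, layer = interId,
                          stringsAsFactors = FALSE)
    }
    net <- multilayerNetwork(rbind(intra, inter),
                             layerIds = seq_len(config$numLayers),
                             interlayerId = interId)
    nodes <- nodeIds(net)
    list(network = net,
         mapping = data.frame(source = nodes, target = nodes,
                              stringsAsFactors = FALSE))
  })
}

#' Remove a fraction of edges uniformly, never isolating a node
#'
#' Produces the "noisy counterpart" of a benchmark network: exactly
#' \code{floor(fraction * |E|)} edges are removed, sampled uniformly over
#' intralayer and interlayer edges together, resampling any candidate whose
#' removal would leave an endpoint isolated. The node set is unchanged.
#'
#' @param net a [MultilayerNetwork-class]
#' @param fraction fraction of edges to remove, in \[0, 1)
#' @param seed optional RNG seed (NULL uses the current stream)
#' @return a perturbed [MultilayerNetwork-class]
#' @export
perturbEdges <- function(net, fraction, seed = NULL) {
  stopifnot(is(net, "MultilayerNetwork"))
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  k <- floor(fraction * edgeCount(net))
  if (k == 0L) return(net)
  .withSeed(seed, {
    e <- net@edges
    nodes <- sort(unique(c(e$u, e$v)))
    deg <- table(factor(c(e$u, e$v), levels = nodes))
    deg <- stats::setNames(as.integer(deg), nodes)
    keep <- rep(TRUE, nrow(e))
    for (i in seq_len(k)) {
      cand <- which(keep & deg[e$u] >= 2L & deg[e$v] >= 2L)
      if (!length(cand))
        stop("cannot remove ", k, " edges without isolating a node")
      j <- cand[sample.int(length(cand), 1L)]
      keep[j] <- FALSE
      deg[e$u[j]] <- deg[e$u[j]] - 1L
      deg[e$v[j]] <- deg[e$v[j]] - 1L
    }
    multilayerNetwork(e[keep, , drop = FALSE], layerIds = net@layerIds,
                      interlayerId = net@interlayerId)
  })
}

#' Noise a similarity matrix in place of the networks
#'
#' For benchmarks where the similarity matrix itself is the input (e.g. a
#' matrix encoding curated biological similarity), noise is applied directly
#' to it: a uniformly sampled fraction of entries is replaced. The default
#' replacement resamples from the empirical distribution of the untouched
#' entries (preserving the value range by construction); \code{method =
#' "jitter"} instead adds Gaussian noise with the untouched entries' SD.
#'
#' @param S a [SimilarityMatrix-class]
#' @param fraction fraction of entries to noise, in \[0, 1)
#' @param seed optional RNG seed
#' @param method \code{"resample"} (default) or \code{"jitter"}
#' @return a [SimilarityMatrix-class] of identical shape and labels
#' @export
perturbSimilarity <- function(S, fraction, seed = NULL,
                              method = c("resample", "jitter")) {
  stopifnot(is(S, "SimilarityMatrix"))
  method <- match.arg(method)
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  v <- S@values
  k <- floor(fraction * length(v))
  if (k == 0L) return(S)
  .withSeed(seed, {
    idx <- sample.int(length(v), k)
    pool <- v[-idx]
    if (method == "resample") {
      for (i in idx) {
        diffpool <- pool[pool != v[i]]
        if (length(diffpool)) v[i] <- sample(diffpool, 1L)
      }
    } else {
      v[idx] <- v[idx] + stats::rnorm(k, sd = stats::sd(pool))
    }
    new("SimilarityMatrix", values = v)
  })
}
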