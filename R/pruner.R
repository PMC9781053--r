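#' Per-filter L1 norms of a convolution weight
#'
#' The pruning saliency: for each filter j (output channel), the sum of
#' the absolute values of all its kernel weights across input channels
#' and both kernel dimensions. Biases are excluded.
#'
#' @param w A 4-way weight array laid out (kh, kw, in, out).
#' @param layer Optional layer id recorded in the table.
#' @return Object of class `filter_norm_table`: `$norms` (length =
#'   output channels), `$layer`, `$n_filters`.
#' @export
#' @examples
#' w <- array(c(1, -2, 0.5, 0), c(2, 2, 1, 1))
#' filter_l1_norms(w)$norms # 3.5
filter_l1_norms <- function(w, layer = NA_character_) {
  if (length(dim(w)) != 4L)
    stop("filter_l1_norms: expected a 4-way (kh, kw, in, out) array, got ",
         if (is.null(dim(w))) "a vector" else paste(dim(w), collapse = "x"))
  cout <- dim(w)[4]
  norms <- colSums(matrix(abs(w), ncol = cout))
  structure(list(layer = layer, norms = norms, n_filters = cout),
            class = "filter_norm_table")
}

#' Select the filters to prune
#'
#' Returns the (1-based) indices of the `m` filters with the smallest
#' L1 norms. Ties keep the lower index (stable order), so the selection
#' is deterministic.
#'
#' @param norms A `filter_norm_table` or a numeric vector of norms.
#' @param m Number of filters to prune; `0 <= m < length(norms)`
#'   (pruning every filter of a layer is refused).
#' @return Sorted integer vector of prune indices (possibly empty).
#' @export
select_filters_to_prune <- function(norms, m) {
  v <- if (inherits(norms, "filter_norm_table")) norms$norms
       else as.numeric(norms)
  m <- as.integer(m)
  if (m < 0L || m >= length(v))
    stop("select_filters_to_prune: m must satisfy 0 <= m < ", length(v),
         " (cannot prune all filters)")
  if (m == 0L) return(integer(0))
  sort(order(v)[seq_len(m)])
}

#' Groups of layers that must share one pruning decision
#'
#' All convolutions whose outputs are summed by a residual addition
#' (the expansion convolution of every block in a stage plus the
#' stage's shortcut projection) must keep the same channels, otherwise
#' the addition is ill-formed; the same channels index the next stage's
#' inputs, the PCE input projections and (for the top stage) the
#' classifier head. Inner bottleneck convolutions are uncoupled and
#' form singleton groups, as does every convolution of a single-path
#' network.
#'
#' @param model A `pcenet_model`.
#' @return Named list of groups; each has `$n` (channel count),
#'   `$producers` (conv weight names producing the channels),
#'   `$norm_source` (the weight ranked for the shared decision) and
#'   `$consumers` (weights sliced along their input axis).
#' @export
coupled_layer_groups <- function(model) {
  stopifnot(inherits(model, "pcenet_model"))
  arch <- model$arch
  groups <- list()
  if (arch$type == "resnet") {
    nst <- length(arch$stages)
    groups[["conv1"]] <- list(
      n = arch$conv1$cout, producers = "conv1.W", norm_source = "conv1.W",
      consumers = c("s1.b1.conv1.W", "s1.b1.down.W"))
    for (i in seq_len(nst)) {
      st <- arch$stages[[i]]
      nb <- length(st$blocks)
      for (j in seq_len(nb)) {
        p <- sprintf("s%d.b%d.", i, j)
        groups[[sprintf("s%d.b%d.w1", i, j)]] <- list(
          n = st$blocks[[j]]$w1, producers = paste0(p, "conv1.W"),
          norm_source = paste0(p, "conv1.W"),
          consumers = paste0(p, "conv2.W"))
        groups[[sprintf("s%d.b%d.w2", i, j)]] <- list(
          n = st$blocks[[j]]$w2, producers = paste0(p, "conv2.W"),
          norm_source = paste0(p, "conv2.W"),
          consumers = paste0(p, "conv3.W"))
      }
      producers <- c(vapply(seq_len(nb),
                            function(j) sprintf("s%d.b%d.conv3.W", i, j), ""),
                     sprintf("s%d.b1.down.W", i))
      # blocks >= 2 within the stage read the stage width; so does the
      # next stage's first block (main and shortcut) or, at the top, the
      # classifier head.
      consumers <- character(0)
      if (nb > 1L)
        consumers <- vapply(2:nb, function(jj)
          sprintf("s%d.b%d.conv1.W", i, jj), "")
      consumers <- c(consumers,
                     if (i < nst)
                       c(sprintf("s%d.b1.conv1.W", i + 1L),
                         sprintf("s%d.b1.down.W", i + 1L))
                     else "head.W")
      if (!is.null(model$config$pce) && i < nst)
        consumers <- c(consumers,
                       vapply(c("fi", "fo", "fs"), function(g)
                         sprintf("pce.l%d.%s.W", i, g), ""))
      if (!is.null(model$config$pce) && i == nst)
        consumers <- c(consumers, "pce.attn.W")
      groups[[sprintf("s%d.out", i)]] <- list(
        n = st$cout, producers = producers,
        norm_source = sprintf("s%d.b%d.conv3.W", i, nb),
        consumers = consumers)
    }
  } else {
    ncv <- length(arch$convs)
    for (i in seq_len(ncv)) {
      groups[[sprintf("c%d", i)]] <- list(
        n = arch$convs[[i]]$cout, producers = sprintf("c%d.W", i),
        norm_source = sprintf("c%d.W", i),
        consumers = if (i < ncv) sprintf("c%d.W", i + 1L) else "head.W")
    }
  }
  groups
}

#' Build an L1 pruning plan
#'
#' For every prunable channel group, ranks the group's norm-source
#' filters by L1 norm and marks the `round(ratio * n)` smallest for
#' removal (round half up, at most `n - 1`). The same global ratio is
#' applied to every layer, so the stage output widths of the default
#' model at ratios 0.25 and 0.5 reproduce the 192/384/768/1536 and
#' 128/256/512/1024 pyramid columns.
#'
#' @param model A `pcenet_model`.
#' @param ratio Fraction of filters to prune per layer, in `[0, 1)`.
#' @return Object of class `pruning_plan`: `$ratio` and `$groups`, each
#'   group with the ordered 1-based keep indices and prune count `m`.
#' @export
build_pruning_plan <- function(model, ratio) {
  stopifnot(inherits(model, "pcenet_model"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0 || ratio >= 1)
    stop("build_pruning_plan: ratio must lie in [0, 1)")
  groups <- coupled_layer_groups(model)
  plan_groups <- lapply(groups, function(g) {
    n <- g$n
    m <- min(as.integer(floor(ratio * n + 0.5)), n - 1L)
    prune <- select_filters_to_prune(
      filter_l1_norms(model$params[[g$norm_source]], g$norm_source), m)
    keep <- setdiff(seq_len(n), prune)
    list(n = n, m = m, keep = keep)
  })
  structure(list(ratio = ratio, groups = plan_groups),
            class = "pruning_plan")
}

# Map each parameter to the group governing its output channels and the
# group governing its input channels (NA = fixed, e.g. RGB input or the
# memory width).
param_group_map <- function(model) {
  groups <- coupled_layer_groups(model)
  out_of <- list(); in_of <- list()
  for (gn in names(groups)) {
    for (pn in groups[[gn]]$producers) out_of[[pn]] <- gn
    for (pn in groups[[gn]]$consumers) in_of[[pn]] <- gn
  }
  list(groups = groups, out_of = out_of, in_of = in_of)
}

#' Apply a pruning plan and rebuild a smaller network
#'
#' Removes the pruned filters together with their biases, batch-norm
#' affine terms and running statistics, slices every consumer layer's
#' kernels on the input-channel axis (including residual partners, the
#' PCE input projections, the attention output and the classifier
#' input), and returns a runnable model at the reduced widths. All
#' surviving weights are copied, never reinitialized. The PCE memory
#' width is deliberately left at its pre-pruning value.
#'
#' @param model A `pcenet_model`.
#' @param plan A [build_pruning_plan()] result (or one read back from
#'   JSON) matching the model's architecture.
#' @return The pruned `pcenet_model`, with `$provenance` recording the
#'   plan ratio.
#' @export
apply_plan <- function(model, plan) {
  stopifnot(inherits(model, "pcenet_model"), inherits(plan, "pruning_plan"))
  pm <- param_group_map(model)
  groups <- pm$groups
  for (gn in names(groups)) {
    pg <- plan$groups[[gn]]
    if (is.null(pg))
      stop("apply_plan: plan has no entry for layer group '", gn, "'")
    if (pg$n != groups[[gn]]$n)
      stop("apply_plan: layer group '", gn, "' has ", groups[[gn]]$n,
           " filters but the plan expects ", pg$n)
    if (length(pg$keep) == 0L || any(pg$keep < 1L) ||
        any(pg$keep > groups[[gn]]$n) || is.unsorted(pg$keep, strictly = TRUE))
      stop("apply_plan: invalid keep indices for layer group '", gn, "'")
  }
  keep_of <- lapply(plan$groups, function(g) as.integer(g$keep))
  nk <- vapply(keep_of, length, 1L)

  arch <- model$arch
  if (arch$type == "resnet") {
    arch$conv1$cout <- nk[["conv1"]]
    for (i in seq_along(arch$stages)) {
      arch$stages[[i]]$cout <- nk[[sprintf("s%d.out", i)]]
      for (j in seq_along(arch$stages[[i]]$blocks)) {
        arch$stages[[i]]$blocks[[j]]$w1 <- nk[[sprintf("s%d.b%d.w1", i, j)]]
        arch$stages[[i]]$blocks[[j]]$w2 <- nk[[sprintf("s%d.b%d.w2", i, j)]]
      }
    }
  } else {
    for (i in seq_along(arch$convs))
      arch$convs[[i]]$cout <- nk[[sprintf("c%d", i)]]
  }
  pce_cfg <- model$config$pce
  new_pce <- NULL
  if (!is.null(pce_cfg)) {
    nst <- length(arch$stages)
    new_widths <- vapply(seq_len(nst),
                         function(i) nk[[sprintf("s%d.out", i)]], 1L)
    new_pce <- pce_config(reduction_ratio = pce_cfg$reduction_ratio,
                          top_channels = new_widths[nst],
                          level_channels = new_widths,
                          memory_dim = pce_cfg$memory_dim)
  }
  new <- build_from_arch(arch, new_pce, seed = 0L)

  keep_idx <- function(gn) if (is.null(gn)) NULL else keep_of[[gn]]
  for (pn in names(model$params)) {
    p <- model$params[[pn]]
    if (grepl("\\.W$", pn) && length(dim(p)) == 4L) {
      ki <- keep_idx(pm$in_of[[pn]])
      ko <- keep_idx(pm$out_of[[pn]])
      if (!is.null(ki)) p <- p[, , ki, , drop = FALSE]
      if (!is.null(ko)) p <- p[, , , ko, drop = FALSE]
    } else if (pn == "head.W") {
      ki <- keep_idx(pm$in_of[[pn]])
      if (!is.null(ki)) p <- p[ki, , drop = FALSE]
    } else if (grepl("^pce\\.l[0-9]+\\.(fi|fo|fs)\\.W$", pn)) {
      lev <- as.integer(sub("^pce\\.l([0-9]+)\\..*$", "\\1", pn))
      p <- p[keep_of[[sprintf("s%d.out", lev)]], , drop = FALSE]
    } else if (pn == "pce.attn.W") {
      p <- p[, keep_of[[sprintf("s%d.out", length(arch$stages))]],
             drop = FALSE]
    } else if (pn == "pce.attn.b") {
      p <- p[keep_of[[sprintf("s%d.out", length(arch$stages))]]]
    } else if (grepl("\\.(gamma|beta)$", pn)) {
      conv <- bn_conv_partner(pn, arch$type)
      ko <- keep_idx(pm$out_of[[conv]])
      if (!is.null(ko)) p <- p[ko]
    }
    new$params[[pn]] <- p
  }
  for (bn in names(model$buffers)) {
    b <- model$buffers[[bn]]
    conv <- bn_conv_partner(bn, arch$type)
    ko <- keep_idx(pm$out_of[[conv]])
    new$buffers[[bn]] <- if (is.null(ko)) b else b[ko]
  }
  new$provenance <- list(ratio = plan$ratio,
                         source_params = length(model$params))
  new
}

# batch-norm parameter/buffer name -> the conv weight whose output
# channels it tracks (the stem and seqcnn share the bare "bnN" pattern,
# so the architecture type disambiguates)
bn_conv_partner <- function(name, arch_type) {
  base <- sub("\\.(gamma|beta|mean|var)$", "", name)
  if (grepl("\\.bn1$", base)) return(sub("bn1$", "conv1.W", base))
  if (grepl("\\.bn2$", base)) return(sub("bn2$", "conv2.W", base))
  if (grepl("\\.bn3$", base)) return(sub("bn3$", "conv3.W", base))
  if (grepl("\\.dbn$", base)) return(sub("dbn$", "down.W", base))
  if (arch_type == "resnet" && base == "bn1") return("conv1.W")
  if (arch_type == "seqcnn" && grepl("^bn[0-9]+$", base))
    return(sub("^bn", "c", paste0(base, ".W")))
  NA_character_
}

#' Serialize a pruning plan to JSON
#'
#' @param plan A `pruning_plan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pruning_plan <- function(plan, path) {
  stopifnot(inherits(plan, "pruning_plan"))
  jsonlite::write_json(list(ratio = plan$ratio, groups = plan$groups),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pruning plan from JSON
#'
#' @param path File written by [write_pruning_plan()].
#' @return A `pruning_plan`.
#' @export
read_pruning_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(j$groups, function(g)
    list(n = as.integer(g$n), m = as.integer(g$m),
         keep = as.integer(g$keep)))
  structure(list(ratio = j$ratio, groups = groups), class = "pruning_plan")
}

#' @export
print.pruning_plan <- function(x, ...) {
  kept <- sum(vapply(x$groups, function(g) length(g$keep), 1L))
  total <- sum(vapply(x$groups, function(g) g$n, 1L))
  cat(sprintf("Pruning plan: ratio %.2f, %d layer groups, keeping %d/%d filters\n",
              x$ratio, length(x$groups), kept, total))
  invisible(x)
}

#' @export
print.filter_norm_table <- function(x, ...) {
  cat(sprintf("Filter L1 norms for layer %s: %d filters, range [%.4g, %.4g]\n",
              x$layer, x$n_filters, min(x$norms), max(x$norms)))
  invisible(x)
}
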