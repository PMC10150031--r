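#' Build a validated feature-pyramid fusion topology
#'
#' Emits the backbone-tap and pyramid-fusion graph as a machine-readable
#' list of feature-level specifications, one per node, for consumption by
#' any training framework.  The backbone taps are the four dense-block
#' outputs of a DenseNet-121 at strides 4/8/16/32 (C2-C5).  Two variants
#' are available:
#'
#' * `"fpn"`: the plain top-down pyramid — each `Pk` (k = 2..5) fuses a
#'   `lateral-1x1` projection of `Ck` with a `topdown-up2` upsampling of
#'   `P(k+1)`; `P6` is a stride-2 pool of `P5`.
#' * `"u-fpn"`: adds a bottom-up multiplexing pathway on top of the
#'   top-down pass.  The top-down intermediates are exposed as `M2`-`M5`;
#'   each output `Pk` (k = 3..6) receives a `bottomup-3x3s2` (3x3 conv,
#'   stride 2) input from the previous output level, and `P3`
#'   additionally receives a `lateral-3x3` edge from `C3`, feeding
#'   shallow detail into every deeper level.  The set of C levels that
#'   contribute extra `lateral-3x3` edges is configurable.
#'
#' Output strides double across the pyramid: P2 = 4 through P6 = 64.
#' The emitted graph is checked to be acyclic.
#'
#' @param variant `"u-fpn"` or `"fpn"`.
#' @param backbone currently `"densenet121-taps"`.
#' @param channels output channels of every pyramid level.
#' @param lateral3x3_from character vector of C levels feeding extra
#'   `lateral-3x3` edges in the u-fpn variant (default `"C3"`).
#' @return a list of class `fpn_topology`; each element is a feature
#'   level with fields `name`, `stride`, `channels` and `fusion_inputs`
#'   (a list of `(source, op)` pairs).
#' @export
build_topology <- function(variant = c("u-fpn", "fpn"),
                           backbone = "densenet121-taps",
                           channels = 256L,
                           lateral3x3_from = "C3") {
  variant <- match.arg(variant)
  if (!identical(backbone, "densenet121-taps"))
    stop("unknown backbone: ", backbone)
  lvl <- function(name, stride, ch, inputs = list())
    list(name = name, stride = as.integer(stride),
         channels = as.integer(unname(ch)),
         fusion_inputs = inputs)
  edge <- function(source, op) list(source = source, op = op)
  tap_channels <- c(C2 = 256L, C3 = 512L, C4 = 1024L, C5 = 1024L)
  nodes <- list(
    lvl("C2", 4L, tap_channels["C2"]), lvl("C3", 8L, tap_channels["C3"]),
    lvl("C4", 16L, tap_channels["C4"]), lvl("C5", 32L, tap_channels["C5"]))
  if (variant == "fpn") {
    nodes <- c(nodes, list(
      lvl("P5", 32L, channels, list(edge("C5", "lateral-1x1"))),
      lvl("P4", 16L, channels, list(edge("C4", "lateral-1x1"),
                                    edge("P5", "topdown-up2"))),
      lvl("P3", 8L, channels, list(edge("C3", "lateral-1x1"),
                                   edge("P4", "topdown-up2"))),
      lvl("P2", 4L, channels, list(edge("C2", "lateral-1x1"),
                                   edge("P3", "topdown-up2"))),
      lvl("P6", 64L, channels, list(edge("P5", "downsample-pool2")))))
  } else {
    nodes <- c(nodes, list(
      lvl("M5", 32L, channels, list(edge("C5", "lateral-1x1"))),
      lvl("M4", 16L, channels, list(edge("C4", "lateral-1x1"),
                                    edge("M5", "topdown-up2"))),
      lvl("M3", 8L, channels, list(edge("C3", "lateral-1x1"),
                                   edge("M4", "topdown-up2"))),
      lvl("M2", 4L, channels, list(edge("C2", "lateral-1x1"),
                                   edge("M3", "topdown-up2"))),
      lvl("P2", 4L, channels, list(edge("M2", "lateral-3x3")))))
    p3_in <- list(edge("M3", "lateral-3x3"), edge("P2", "bottomup-3x3s2"))
    for (cl in lateral3x3_from) p3_in <- c(p3_in, list(edge(cl, "lateral-3x3")))
    nodes <- c(nodes, list(
      lvl("P3", 8L, channels, p3_in),
      lvl("P4", 16L, channels, list(edge("M4", "lateral-3x3"),
                                    edge("P3", "bottomup-3x3s2"))),
      lvl("P5", 32L, channels, list(edge("M5", "lateral-3x3"),
                                    edge("P4", "bottomup-3x3s2"))),
      lvl("P6", 64L, channels, list(edge("P5", "bottomup-3x3s2")))))
  }
  topo <- structure(nodes, class = "fpn_topology")
  if (!topology_is_dag(topo)) stop("internal error: topology has a cycle")
  topo
}

#' Check that a topology's fusion graph is acyclic
#' @param topo an `fpn_topology`.
#' @return `TRUE` if the graph admits a topological order.
#' @export
topology_is_dag <- function(topo) {
  names_ <- vapply(topo, `[[`, character(1L), "name")
  deps <- lapply(topo, function(nd)
    vapply(nd$fusion_inputs, `[[`, character(1L), "source"))
  done <- character(0L)
  repeat {
    ready <- names_[!names_ %in% done &
                    vapply(seq_along(names_), function(i)
                      all(deps[[i]] %in% done), logical(1L))]
    if (!length(ready)) break
    done <- c(done, ready)
  }
  length(done) == length(names_)
}

#' Strides of the pyramid output levels
#' @param topo an `fpn_topology`.
#' @return named integer vector of strides for P2..P6.
#' @export
topology_strides <- function(topo) {
  nm <- vapply(topo, `[[`, character(1L), "name")
  p <- grepl("^P", nm)
  out <- vapply(topo[p], `[[`, integer(1L), "stride")
  names(out) <- nm[p]
  out[order(names(out))]
}

#' Serialize / read a topology as JSON
#'
#' The JSON round-trip is lossless: `read_topology_json()` of a written
#' file reproduces the original object.
#'
#' @param topo an `fpn_topology`.
#' @param path output (input) JSON file path.
#' @export
write_topology_json <- function(topo, path) {
  jsonlite::write_json(unclass(topo), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- lapply(raw, function(nd)
    list(name = nd$name, stride = as.integer(nd$stride),
         channels = as.integer(nd$channels),
         fusion_inputs = lapply(nd$fusion_inputs, function(e)
           list(source = e$source, op = e$op))))
  structure(nodes, class = "fpn_topology")
}
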