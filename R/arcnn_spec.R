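# ARCNN topology: aggregated residual block specs, the staged network spec,
# and the analytic shape propagator that reproduces the printed topology
# without allocating any tensors.

#' Convolution output side length
#'
#' Standard convolution arithmetic for cubic inputs:
#' `floor((in_side + 2*p - k) / s) + 1`.
#'
#' @param in_side Input side length.
#' @param k Kernel size.
#' @param s Stride.
#' @param p Padding.
#' @return The output side length.
#' @examples
#' conv_output_side(256, 7, 2, 3)  # 128
#' @export
conv_output_side <- function(in_side, k, s = 1L, p = 0L) {
  stopifnot(in_side >= 1, k >= 1, s >= 1, p >= 0)
  if (any(in_side + 2 * p < k)) {
    stop("kernel larger than padded input", call. = FALSE)
  }
  as.integer(floor((in_side + 2 * p - k) / s) + 1)
}

#' Aggregated residual block specification
#'
#' One bottleneck residual block with an aggregated (grouped) 3x3x3
#' transform: 1x1x1 reduce to the bottleneck width, grouped 3x3x3 with
#' cardinality `C` branches, 1x1x1 expand. The bottleneck width is the
#' total grouped width (per-branch width times `C`).
#'
#' @param in_channels,bottleneck_channels,out_channels Channel widths.
#' @param cardinality_C Number of branches (groups).
#' @param kernel Spatial kernel of the grouped transform (odd).
#' @param stride Stride of the grouped transform (1 or 2).
#' @param padding Padding of the grouped transform.
#' @return An object of class `arb_spec`.
#' @export
arb_spec <- function(in_channels, bottleneck_channels, out_channels,
                     cardinality_C = 8L, kernel = 3L, stride = 1L,
                     padding = 1L) {
  stopifnot(in_channels >= 1, bottleneck_channels >= 1, out_channels >= 1,
            cardinality_C >= 1, kernel %% 2 == 1, stride %in% c(1L, 2L),
            padding >= 0)
  if (bottleneck_channels %% cardinality_C != 0) {
    stop("bottleneck_channels must be divisible by cardinality_C",
         call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 out_channels = as.integer(out_channels),
                 cardinality_C = as.integer(cardinality_C),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 padding = as.integer(padding)),
            class = "arb_spec")
}

#' ARCNN network specification
#'
#' The staged topology of the volumetric diagnosis network: a 7x7x7
#' stride-2 stem convolution with batch normalization, 3x3x3 stride-2 max
#' pooling, four aggregated-residual stages with block repeats
#' (3, 4, 6, 3), global average pooling and a two-layer fully connected
#' head ending in `num_classes` logits. Stage strides are 1 for the first
#' residual stage and 2 (first block) for the remaining three, giving five
#' spatial halvings overall, so `input_side` must be divisible by 32.
#'
#' The default widths reproduce the full-scale printed topology
#' (input 256^3, stem 64 channels, stage outputs 256/512/1024/2048,
#' grouped bottleneck widths 32/64/128/256 = per-branch 4/8/16/32 times
#' cardinality 8, head 2048 -> 512 -> 2). [arcnn_spec_scaled()] divides all
#' widths for desk-scale training.
#'
#' @param input_side Cube side length of the input volume.
#' @param input_channels Number of input channels.
#' @param conv1_channels Stem output channels.
#' @param bottleneck_widths Grouped bottleneck widths per stage (length 4).
#' @param stage_channels Stage output widths (length 4).
#' @param stage_repeats Blocks per stage (length 4).
#' @param cardinality Branch count `C` of every block.
#' @param fc_width Width of the first fully connected layer.
#' @param num_classes Number of output logits.
#' @return An object of class `arcnn_spec`.
#' @examples
#' arcnn_stage_shapes(arcnn_spec())
#' @export
arcnn_spec <- function(input_side = 256L, input_channels = 1L,
                       conv1_channels = 64L,
                       bottleneck_widths = c(32L, 64L, 128L, 256L),
                       stage_channels = c(256L, 512L, 1024L, 2048L),
                       stage_repeats = c(3L, 4L, 6L, 3L),
                       cardinality = 8L, fc_width = 512L,
                       num_classes = 2L) {
  stopifnot(length(bottleneck_widths) == 4, length(stage_channels) == 4,
            length(stage_repeats) == 4, all(stage_repeats >= 1),
            input_side >= 32, input_channels >= 1, num_classes >= 2)
  if (input_side %% 32 != 0) {
    stop("input_side must be divisible by 32 (five spatial halvings)",
         call. = FALSE)
  }
  if (any(bottleneck_widths %% cardinality != 0)) {
    stop("bottleneck widths must be divisible by the cardinality",
         call. = FALSE)
  }
  structure(list(input_side = as.integer(input_side),
                 input_channels = as.integer(input_channels),
                 conv1_channels = as.integer(conv1_channels),
                 bottleneck_widths = as.integer(bottleneck_widths),
                 stage_channels = as.integer(stage_channels),
                 stage_repeats = as.integer(stage_repeats),
                 cardinality = as.integer(cardinality),
                 fc_width = as.integer(fc_width),
                 num_classes = as.integer(num_classes),
                 stage_strides = c(1L, 2L, 2L, 2L)),
            class = "arcnn_spec")
}

#' Desk-scale ARCNN specification
#'
#' The default topology with all channel widths divided by `divisor` and a
#' smaller input cube; used for training on synthetic phantoms where the
#' full-scale network would be needlessly large.
#'
#' @param input_side Input cube side (divisible by 32).
#' @param divisor Width divisor applied to every channel count.
#' @return An `arcnn_spec`.
#' @export
arcnn_spec_scaled <- function(input_side = 32L, divisor = 8L) {
  stopifnot(divisor >= 1, 64 %% divisor == 0)
  arcnn_spec(input_side = input_side,
             conv1_channels = 64L %/% divisor,
             # grouped widths stay divisible by the cardinality (>= 1 branch
             # channel), so the narrowest stage is floored at 8
             bottleneck_widths = as.integer(pmax(c(32, 64, 128, 256) %/%
                                                   divisor, 8L)),
             stage_channels = as.integer(c(256, 512, 1024, 2048) %/% divisor),
             cardinality = 8L,
             fc_width = 512L %/% divisor)
}

#' Analytic layer shapes of an ARCNN
#'
#' Propagates input shapes through the staged topology purely
#' arithmetically (no tensor allocation): one row per stage — stem
#' convolution, max pool, the four residual stages, global average pooling
#' and the two fully connected layers. For the default spec the rows
#' reproduce the printed full-scale topology exactly.
#'
#' @param spec An [arcnn_spec()].
#' @return A tibble with columns `stage`, `in_side`, `in_channels`,
#'   `out_side`, `out_channels`. Fully connected rows use side 1.
#' @examples
#' arcnn_stage_shapes(arcnn_spec_scaled())
#' @export
arcnn_stage_shapes <- function(spec) {
  stopifnot(inherits(spec, "arcnn_spec"))
  rows <- list()
  side <- spec$input_side
  ch <- spec$input_channels

  out_side <- conv_output_side(side, 7L, 2L, 3L)
  rows[[1]] <- list("conv1", side, ch, out_side, spec$conv1_channels)
  side <- out_side; ch <- spec$conv1_channels

  out_side <- conv_output_side(side, 3L, 2L, 1L)
  rows[[2]] <- list("max_pool", side, ch, out_side, ch)
  side <- out_side

  for (s in 1:4) {
    stride <- spec$stage_strides[s]
    out_side <- if (stride == 2L) conv_output_side(side, 3L, 2L, 1L) else side
    rows[[2 + s]] <- list(paste0("conv", s + 1), side, ch, out_side,
                          spec$stage_channels[s])
    side <- out_side; ch <- spec$stage_channels[s]
  }

  rows[[7]] <- list("GAP", side, ch, 1L, ch)
  rows[[8]] <- list("FC1", 1L, ch, 1L, spec$fc_width)
  rows[[9]] <- list("FC2", 1L, spec$fc_width, 1L, spec$num_classes)

  tibble::tibble(
    stage = vapply(rows, `[[`, character(1), 1),
    in_side = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    in_channels = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    out_side = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    out_channels = vapply(rows, function(r) as.integer(r[[5]]), integer(1))
  )
}

#' @export
print.arcnn_spec <- function(x, ...) {
  cat(sprintf("<arcnn_spec> input %d^3 x %d, cardinality %d, classes %d\n",
              x$input_side, x$input_channels, x$cardinality, x$num_classes))
  print(arcnn_stage_shapes(x))
  invisible(x)
}

# Per-block arb_spec list for a stage, first block carrying the stage stride
# and (usually) a projection shortcut.
.stage_blocks <- function(spec, stage) {
  in_ch <- if (stage == 1) spec$conv1_channels else
    spec$stage_channels[stage - 1]
  out_ch <- spec$stage_channels[stage]
  bott <- spec$bottleneck_widths[stage]
  lapply(seq_len(spec$stage_repeats[stage]), function(b) {
    arb_spec(in_channels = if (b == 1) in_ch else out_ch,
             bottleneck_channels = bott,
             out_channels = out_ch,
             cardinality_C = spec$cardinality,
             stride = if (b == 1) spec$stage_strides[stage] else 1L)
  })
}
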