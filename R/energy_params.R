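# Nearest-neighbour free-energy parameters for perfect stem-loops.
# The shipped tables carry the published Turner 2004 constants
# (37 degrees C, kcal/mol): stacking energies for Watson-Crick and G:U
# wobble pair steps, hairpin-loop initiation by loop size, and replacement
# energies for tabulated stable tetraloops.

.param_cache <- new.env(parent = emptyenv())

#' Load nearest-neighbour energy parameters
#'
#' Reads the stacking, hairpin-loop-initiation and tetraloop tables shipped
#' with the package (or user-supplied files in the same format) into a
#' lookup structure used by \code{\link{hairpin_energy}}.
#'
#' @param stack_file,loop_file,tetraloop_file optional TSV paths overriding
#'   the shipped tables.  \code{stack_file} columns: \code{outer_pair},
#'   \code{inner_pair} (each one of CG, GC, GU, UG, AU, UA, read 5' base
#'   then 3' base), \code{dG}.  \code{loop_file} columns: \code{loop_len},
#'   \code{dG}.  \code{tetraloop_file} columns: \code{context} (closing 5'
#'   base + 4 loop bases + closing 3' base), \code{dG}.
#' @return object of class \code{energy_parameters}: list with
#'   \code{stack} (named numeric, names \code{"<outer>:<inner>"}),
#'   \code{loop} (numeric indexed by loop length), \code{tetraloop}
#'   (named numeric), \code{version}.
#' @export
energy_parameters <- function(stack_file = NULL, loop_file = NULL,
                              tetraloop_file = NULL) {
  default <- is.null(stack_file) && is.null(loop_file) &&
    is.null(tetraloop_file)
  if (default && !is.null(.param_cache$default)) return(.param_cache$default)
  pth <- function(user, name) {
    if (!is.null(user)) user
    else system.file("extdata", name, package = "colligator",
                     mustWork = TRUE)
  }
  stack_df <- read.delim(pth(stack_file, "nn_stack_turner2004.tsv"))
  loop_df <- read.delim(pth(loop_file, "nn_hairpin_loop_turner2004.tsv"))
  tetra_df <- read.delim(pth(tetraloop_file, "nn_tetraloop_turner2004.tsv"))
  stopifnot(all(c("outer_pair", "inner_pair", "dG") %in% names(stack_df)),
            all(c("loop_len", "dG") %in% names(loop_df)),
            all(c("context", "dG") %in% names(tetra_df)))
  loop <- rep(NA_real_, max(loop_df$loop_len))
  loop[loop_df$loop_len] <- loop_df$dG
  params <- structure(list(
    stack = setNames(stack_df$dG,
                     paste0(stack_df$outer_pair, ":", stack_df$inner_pair)),
    loop = loop,
    tetraloop = setNames(tetra_df$dG, tetra_df$context),
    version = "turner2004"), class = "energy_parameters")
  if (default) .param_cache$default <- params
  params
}

# canonical pair set used throughout hairpin code (WC + GU wobble)
.pair_types <- c("AU", "UA", "GC", "CG", "GU", "UG")

.can_pair <- function(x, y) paste0(x, y) %in% .pair_types
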