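# Method registry: the evaluation grid runs any registered method by name.
# External compositional methods (LOCOM, ANCOM-BC, fastANCOM, LinDA,
# ALDEx2, DACOMP, WRENCH, ...) plug in through this adapter interface; the
# package itself only bundles the Wilcoxon alr variants.

.da_registry <- new.env(parent = emptyenv())

#' Register a differential-abundance method
#'
#' An adapter is a function `function(dataset, level, presence_fraction)`
#' returning a [da_result()]. Registered methods become selectable in
#' [run_grid()]. An adapter that errors on a replicate causes that
#' replicate to be logged as failed for the method; the grid continues.
#'
#' @param name Unique method name.
#' @param fun Adapter function.
#' @param overwrite Allow replacing an existing registration?
#' @return `name`, invisibly.
#' @export
#' @examples
#' register_da_method("reject-nothing",
#'   function(dataset, level, presence_fraction) {
#'     kept <- filter_rare_taxa(dataset$counts, presence_fraction)
#'     da_result(kept, rep(1, length(kept)), rep(1, length(kept)),
#'               "reject-nothing", level)
#'   }, overwrite = TRUE)
register_da_method <- function(name, fun, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  if (!overwrite && exists(name, envir = .da_registry, inherits = FALSE)) {
    stop("method \"", name, "\" is already registered")
  }
  assign(name, fun, envir = .da_registry)
  invisible(name)
}

#' List registered method names
#' @return Character vector of registered method names.
#' @export
da_methods <- function() sort(ls(.da_registry))

#' Look up a registered method
#' @param name Method name.
#' @return The adapter function.
#' @export
get_da_method <- function(name) {
  if (!exists(name, envir = .da_registry, inherits = FALSE)) {
    stop("unknown method \"", name, "\"; registered methods: ",
         paste(da_methods(), collapse = ", "))
  }
  get(name, envir = .da_registry)
}

register_builtin_methods <- function() {
  register_da_method("wilcox-alr-half",
                     function(dataset, level, presence_fraction) {
                       run_wilcox_alr(dataset, 0.5, presence_fraction, level)
                     }, overwrite = TRUE)
  register_da_method("wilcox-alr-one",
                     function(dataset, level, presence_fraction) {
                       run_wilcox_alr(dataset, 1, presence_fraction, level)
                     }, overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_methods()
}
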