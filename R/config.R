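# YAML round-tripping for the three configuration families, used by the
# command-line interface (inst/cli/rapecount.R) and batch runs.

#' Read a YAML configuration file
#'
#' The file may hold any of the sections `network`, `train` and `scene`;
#' each is merged over the corresponding constructor's defaults
#' ([network_config()], [train_config()], [scene_config()]).
#'
#' @param path YAML file path.
#' @return A list with elements `network`, `train`, `scene`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    network = do.call(network_config, raw$network %||% list()),
    train = do.call(train_config, raw$train %||% list()),
    scene = do.call(scene_config, raw$scene %||% list())
  )
}

#' Write configurations to YAML
#'
#' @param path Output path.
#' @param network,train,scene Configuration objects (or `NULL` to omit).
#' @return `path`, invisibly.
#' @export
write_config <- function(path, network = NULL, train = NULL, scene = NULL) {
  strip <- function(x, drop = character(0)) {
    if (is.null(x)) return(NULL)
    x <- unclass(x)
    x[setdiff(names(x), c("output_stride", drop))]
  }
  yaml::write_yaml(list(network = strip(network),
                        train = strip(train),
                        scene = strip(scene, "profile")),
                   path)
  invisible(path)
}
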