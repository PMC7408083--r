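PANEL_ROLES <- c("mesenchymal", "epithelial", "caf", "signature")

CAF_GENES <- c("FN1", "TGFB2", "TGFBR2", "TGFBI")

#' Construct a gene panel
#'
#' A named signature: gene symbols with roles. Roles are `mesenchymal` /
#' `epithelial` (the 14-gene EMT score), `caf` (the 4-gene CAF index), or
#' `signature` (the 76-gene CDH1-weighted score, whose weights are
#' computed per cohort, not stored).
#'
#' Named default panels are count-validated: `caf4` must be exactly
#' \{FN1, TGFB2, TGFBR2, TGFBI\}; `emt_salt14` must carry exactly 9
#' mesenchymal and 5 epithelial genes; `emt76gs` exactly 76 genes
#' including CDH1.
#'
#' @param name panel name (validation is strict for the default names).
#' @param symbols character gene symbols, no duplicates.
#' @param roles one role per gene, from the role enum.
#' @return object of class `gene_panel`.
#' @export
gene_panel <- function(name, symbols, roles) {
  symbols <- as.character(symbols)
  roles <- as.character(roles)
  if (length(symbols) != length(roles))
    stop("one role per symbol required", call. = FALSE)
  bad <- setdiff(unique(roles), PANEL_ROLES)
  if (length(bad))
    stop("unknown panel role(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(PANEL_ROLES, collapse = ", "), ")",
         call. = FALSE)
  if (anyDuplicated(symbols))
    stop("duplicate gene symbol(s) in panel '", name, "': ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "),
         call. = FALSE)

  p <- structure(list(name = name, symbols = symbols, roles = roles),
                 class = "gene_panel")
  validate_default_panel(p)
  p
}

validate_default_panel <- function(p) {
  if (identical(p$name, "caf4")) {
    if (!setequal(p$symbols, CAF_GENES) || !all(p$roles == "caf"))
      stop("panel 'caf4' must contain exactly FN1, TGFB2, TGFBR2, TGFBI ",
           "with role 'caf'", call. = FALSE)
  } else if (identical(p$name, "emt_salt14")) {
    n_mes <- sum(p$roles == "mesenchymal")
    n_epi <- sum(p$roles == "epithelial")
    if (n_mes != 9L || n_epi != 5L)
      stop("panel 'emt_salt14' needs 9 mesenchymal + 5 epithelial genes; ",
           "got ", n_mes, " mesenchymal and ", n_epi, " epithelial",
           call. = FALSE)
  } else if (identical(p$name, "emt76gs")) {
    if (length(p$symbols) != 76L)
      stop("panel 'emt76gs' needs exactly 76 genes; got ",
           length(p$symbols), call. = FALSE)
    if (!"CDH1" %in% p$symbols)
      stop("panel 'emt76gs' must include CDH1 (the weighting anchor)",
           call. = FALSE)
  }
  invisible(p)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %s: %d genes (%s)\n", x$name, length(x$symbols),
              paste(sprintf("%d %s", table(x$roles), names(table(x$roles))),
                    collapse = ", ")))
  invisible(x)
}

#' Genes of a panel by role
#' @param panel a [gene_panel]
#' @param role one of the role enum values
#' @return character vector of symbols
#' @export
panel_genes <- function(panel, role = NULL) {
  if (is.null(role)) return(panel$symbols)
  panel$symbols[panel$roles == role]
}

#' Load a gene panel from a two-column TSV
#'
#' Format: tab-separated `symbol` and `role` columns, `#` comment lines
#' allowed. The panel name defaults to the file stem, which makes the
#' bundled defaults (`caf4`, `emt_salt14`, `emt76gs`) count-validated on
#' load.
#'
#' @param path panel file
#' @param name panel name; default the file name without extension
#' @return a [gene_panel]
#' @export
load_panel <- function(path, name = NULL) {
  if (!file.exists(path))
    stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("symbol", "role") %in% names(df)))
    stop("panel file needs 'symbol' and 'role' columns: ", path,
         call. = FALSE)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  gene_panel(name, df$symbol, df$role)
}

#' Built-in default panels
#'
#' `"caf4"`: the 4-gene CAF index \{FN1, TGFB2, TGFBR2, TGFBI\}.
#' `"emt_salt14"`: the 14-gene EMT score panel (9 mesenchymal, 5
#' epithelial). `"emt76gs"`: 76 genes for the CDH1-correlation-weighted
#' score. FN1 is the only gene shared between `caf4` and `emt_salt14`.
#'
#' @param which one of `"caf4"`, `"emt_salt14"`, `"emt76gs"`
#' @return a [gene_panel]
#' @export
default_panel <- function(which = c("caf4", "emt_salt14", "emt76gs")) {
  which <- match.arg(which)
  path <- system.file("extdata", "panels", paste0(which, ".tsv"),
                      package = "cafindex", mustWork = TRUE)
  load_panel(path, name = which)
}
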