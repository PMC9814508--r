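#' Parse an architecture structure string
#'
#' Architectures are written as dash-separated layer tokens in the notation
#' used for network summary tables:
#' `Conv [x, (y, z)]` (2-D convolution, x filters, y-by-z kernel),
#' `SeparableConv [x, (y, z)]` (depthwise-separable convolution),
#' `BN` (batch normalisation), `MaxPooling (y, z)`, `Drop (r)` (dropout),
#' `FC(u)` / `Dense (u)` (fully connected), `LSTM (u)`, `GRU (u)`,
#' `GlobalAveragePooling ()`, `residual {...}` (start of a residual block
#' whose projection branch is the brace content) and `add` (the matching
#' merge point). Tokens are case-insensitive and whitespace-tolerant.
#'
#' @param s Structure string.
#' @return A list of layer specs, each a list with `kind` and parameters;
#'   `residual_branch_start` entries carry a `branch` sub-list.
#' @export
parse_structure <- function(s) {
  if (!is.character(s) || length(s) != 1 || !nzchar(trimws(s))) {
    stop("parse error: empty structure string", call. = FALSE)
  }
  tokens <- split_top_level(s)
  layers <- lapply(tokens, parse_token)
  depth <- 0L
  for (ly in layers) {
    if (ly$kind == "residual_branch_start") depth <- depth + 1L
    if (ly$kind == "add_residual") {
      depth <- depth - 1L
      if (depth < 0) {
        stop("parse error: 'add' without a matching 'residual {...}'",
             call. = FALSE)
      }
    }
  }
  if (depth != 0) {
    stop("parse error: ", depth, " residual block(s) never closed by 'add'",
         call. = FALSE)
  }
  layers
}

# split on "-" except inside (), [] or {}
split_top_level <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[", "{")) depth <- depth + 1L
    if (ch %in% c(")", "]", "}")) {
      depth <- depth - 1L
      if (depth < 0) {
        stop("parse error: unbalanced bracket at position ", i, call. = FALSE)
      }
    }
    if (ch == "-" && depth == 0L) cuts <- c(cuts, i)
  }
  if (depth != 0L) {
    stop("parse error: unbalanced brackets in structure string",
         call. = FALSE)
  }
  bounds <- c(0L, cuts, length(chars) + 1L)
  toks <- vapply(seq_len(length(bounds) - 1L), function(j) {
    trimws(paste(chars[seq(bounds[j] + 1L, bounds[j + 1L] - 1L)],
                 collapse = ""))
  }, character(1))
  toks[nzchar(toks)]
}

num_args <- function(tok) {
  m <- regmatches(tok, gregexpr("-?[0-9]+\\.?[0-9]*", tok))[[1]]
  as.numeric(m)
}

parse_token <- function(tok) {
  low <- tolower(gsub("\\s+", "", tok))
  if (grepl("^residual\\{", low)) {
    inner <- sub("^\\s*residual\\s*\\{", "", tok)
    inner <- sub("\\}\\s*$", "", inner)
    return(list(kind = "residual_branch_start",
                branch = parse_structure(inner)))
  }
  if (grepl("^separableconv", low)) {
    a <- num_args(tok)
    if (length(a) != 3) stop("parse error in token '", tok, "'", call. = FALSE)
    return(list(kind = "separable_conv2d", filters = as.integer(a[1]),
                kernel = as.integer(a[2:3])))
  }
  if (grepl("^conv", low)) {
    a <- num_args(tok)
    if (length(a) != 3) stop("parse error in token '", tok, "'", call. = FALSE)
    return(list(kind = "conv2d", filters = as.integer(a[1]),
                kernel = as.integer(a[2:3])))
  }
  if (low == "bn") return(list(kind = "batch_norm"))
  if (grepl("^maxpooling", low)) {
    a <- num_args(tok)
    if (length(a) != 2) stop("parse error in token '", tok, "'", call. = FALSE)
    return(list(kind = "max_pool", pool = as.integer(a)))
  }
  if (grepl("^globalaveragepooling", low)) {
    return(list(kind = "global_avg_pool"))
  }
  if (grepl("^drop", low)) {
    a <- num_args(tok)
    if (length(a) != 1 || a[1] < 0 || a[1] >= 1) {
      stop("parse error in token '", tok, "'", call. = FALSE)
    }
    return(list(kind = "dropout", rate = a[1]))
  }
  if (grepl("^(fc|dense)", low)) {
    a <- num_args(tok)
    if (length(a) != 1) stop("parse error in token '", tok, "'", call. = FALSE)
    return(list(kind = "dense", units = as.integer(a[1])))
  }
  if (grepl("^lstm", low)) {
    a <- num_args(tok)
    if (length(a) != 1) stop("parse error in token '", tok, "'", call. = FALSE)
    return(list(kind = "lstm", units = as.integer(a[1])))
  }
  if (grepl("^gru", low)) {
    a <- num_args(tok)
    if (length(a) != 1) stop("parse error in token '", tok, "'", call. = FALSE)
    return(list(kind = "gru", units = as.integer(a[1])))
  }
  if (low %in% c("add")) return(list(kind = "add_residual"))
  stop("parse error: unknown token '", tok, "'", call. = FALSE)
}

#' Render a parsed layer list back to a structure string
#'
#' Inverse of [parse_structure()]; round-tripping is exact up to whitespace.
#'
#' @param layers Layer list from [parse_structure()].
#' @return A single structure string.
#' @export
deparse_structure <- function(layers) {
  tok <- vapply(layers, function(ly) {
    switch(ly$kind,
      conv2d = sprintf("Conv [%d, (%d,%d)]", ly$filters, ly$kernel[1],
                       ly$kernel[2]),
      separable_conv2d = sprintf("SeparableConv [%d, (%d,%d)]", ly$filters,
                                 ly$kernel[1], ly$kernel[2]),
      batch_norm = "BN",
      max_pool = sprintf("MaxPooling (%d,%d)", ly$pool[1], ly$pool[2]),
      dropout = sprintf("Drop (%g)", ly$rate),
      dense = sprintf("FC(%d)", ly$units),
      lstm = sprintf("LSTM (%d)", ly$units),
      gru = sprintf("GRU (%d)", ly$units),
      global_avg_pool = "GlobalAveragePooling ()",
      add_residual = "add",
      residual_branch_start = sprintf("residual {%s}",
                                      deparse_structure(ly$branch)),
      stop("unknown layer kind: ", ly$kind, call. = FALSE)
    )
  }, character(1))
  paste(tok, collapse = "-")
}
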