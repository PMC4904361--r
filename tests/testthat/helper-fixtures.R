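# Shared, lazily computed fixtures. Heavy objects (the full library, the class
# map, scaled-down training runs) are built once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_library <- function() fixture("lib", function() poly_library())

test_class_map <- function() fixture("cm", function()
  find_duplicate_profiles(test_library()))

test_solid <- function(name) {
  lib <- test_library()
  nm <- vapply(lib, function(p) p$name, character(1))
  lib[[match(name, nm)]]
}

# rotation taking the cube body diagonal (1,1,1)/sqrt(3) to the z-axis
body_diagonal_phi <- function() {
  phiy <- asin(-1 / sqrt(3))
  phix <- atan2(1 / sqrt(3), 1 / sqrt(3))
  c(phix, phiy)
}

# ids of solids with at most `cap` vertices
ids_with_cap <- function(cap = 20) {
  lib <- test_library()
  ids <- vapply(lib, function(p) p$id, integer(1))
  nv <- vapply(lib, function(p) nrow(p$vertices), integer(1))
  ids[nv <= cap]
}
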