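# Building anterior-bite load cases on skull meshes: the bite node is
# constrained dorsoventrally, the jaw-joint node in all directions, and
# the scaled muscle force is split between the temporal and quadrate
# adductor groups across their attachment nodes.

#' Index of the mesh node nearest to a point
#'
#' @param mesh A [planar_mesh()].
#' @param point Length-2 (x, y) in mm.
#' @return Integer node index.
#' @export
nearest_node <- function(mesh, point) {
  d2 <- (mesh$nodes[, 1] - point[1])^2 + (mesh$nodes[, 2] - point[2])^2
  which.min(d2)
}

#' Boundary node indices of a mesh
#'
#' Nodes lying on edges that belong to exactly one triangle.
#'
#' @param mesh A [planar_mesh()].
#' @return Sorted integer vector of node indices.
#' @export
boundary_nodes <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  k <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(k) == 1))
  sort(unique(as.integer(unlist(strsplit(once, " ")))))
}

#' Mesh nodes near a point
#'
#' @param mesh A [planar_mesh()].
#' @param point Length-2 centre (mm).
#' @param radius Search radius (mm).
#' @param boundary_only Restrict to boundary nodes (muscle attachments sit
#'   on the skull surface)?
#' @return Integer node indices (at least the single nearest node).
#' @export
nodes_near <- function(mesh, point, radius, boundary_only = TRUE) {
  cand <- if (boundary_only) boundary_nodes(mesh) else seq_len(nrow(mesh$nodes))
  d2 <- (mesh$nodes[cand, 1] - point[1])^2 +
        (mesh$nodes[cand, 2] - point[2])^2
  hit <- cand[d2 <= radius^2]
  if (length(hit) == 0) hit <- cand[which.min(d2)]
  hit
}

#' Anterior-bite load case
#'
#' Constrains the bite node dorsoventrally (y) and the jaw-joint node in
#' all directions, then applies the total (already area-scaled) muscle
#' force split between the temporal and quadrate groups by `partition`
#' (temporal fraction; 0.5/0.5 by default). Within a group the force is
#' divided equally among the attachment nodes, each nodal force directed
#' from the node toward the group's insertion target on the lower jaw.
#' The nodal force magnitudes sum to `total_force` exactly.
#'
#' @param mesh A [planar_mesh()].
#' @param bite_point,joint_point (x, y) mm; snapped to the nearest node.
#' @param temporal_nodes,quadrate_nodes Attachment node indices.
#' @param temporal_target,quadrate_target Insertion points (x, y) mm.
#' @param total_force Total muscle force (N), e.g. from [scale_force()].
#' @param partition Temporal-group fraction of the total force, in [0, 1].
#' @return A [load_case()].
#' @export
bite_load_case <- function(mesh, bite_point, joint_point,
                           temporal_nodes, temporal_target,
                           quadrate_nodes, quadrate_target,
                           total_force, partition = 0.5) {
  if (partition < 0 || partition > 1) abort("partition must be in [0, 1]")
  if (total_force <= 0) abort("total_force must be positive")
  bite <- nearest_node(mesh, bite_point)
  joint <- nearest_node(mesh, joint_point)
  if (bite == joint) abort("bite and joint collapse onto one node")
  group_loads <- function(nodes, target, f_group) {
    nodes <- setdiff(nodes, c(bite, joint))
    if (length(nodes) == 0) abort("muscle group has no free attachment nodes")
    per <- f_group / length(nodes)
    dir <- cbind(target[1] - mesh$nodes[nodes, 1],
                 target[2] - mesh$nodes[nodes, 2])
    nrm <- sqrt(rowSums(dir^2))
    if (any(nrm == 0)) abort("attachment node coincides with insertion target")
    tibble(node = nodes, fx = per * dir[, 1] / nrm, fy = per * dir[, 2] / nrm)
  }
  loads <- dplyr::bind_rows(
    if (partition > 0) group_loads(temporal_nodes, temporal_target,
                                   total_force * partition),
    if (partition < 1) group_loads(quadrate_nodes, quadrate_target,
                                   total_force * (1 - partition)))
  load_case(
    fixed = tibble(node = c(bite, joint), dir = c("y", "both")),
    loads = loads)
}
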