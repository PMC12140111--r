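#include <Rcpp.h>
using namespace Rcpp;

// Triangulated Maximally Filtered Graph on a symmetric similarity matrix.
//
// Greedy construction: seed with the 4 nodes of largest off-diagonal
// row sum (K4), keep the list of triangular faces, and repeatedly insert
// the unplaced node v into the face (x,y,z) with the largest gain
// w(v,x)+w(v,y)+w(v,z), replacing that face by three new ones.  The
// result has exactly 3n-6 edges and is planar by construction (its face
// list is a triangulation certificate).
//
// Ties are broken deterministically: seed selection by stable sort on
// (-rowsum, index); insertion by lowest node index, then earliest
// created face.  Indices in the returned matrices are 1-based.
// [[Rcpp::export(name = ".tmfg_cpp")]]
List tmfg_cpp(NumericMatrix w) {
  const int n = w.nrow();
  if (n < 4) stop("TMFG requires >= 4 nodes");

  std::vector<double> rs(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) rs[i] += w(i, j);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return rs[a] > rs[b]; });
  std::vector<int> seed(idx.begin(), idx.begin() + 4);
  std::sort(seed.begin(), seed.end());

  const int n_edges = 3 * n - 6;
  const int max_faces = (n == 4) ? 4 : 3 * n - 8;  // created over the run
  IntegerMatrix edges(n_edges, 2);
  int ne = 0;
  std::vector<std::array<int, 3>> faces;
  faces.reserve(max_faces);
  std::vector<bool> face_active;
  face_active.reserve(max_faces);

  for (int a = 0; a < 4; ++a)
    for (int b = a + 1; b < 4; ++b) {
      edges(ne, 0) = seed[a] + 1;
      edges(ne, 1) = seed[b] + 1;
      ++ne;
    }
  // 4 faces of the tetrahedron
  for (int skip = 3; skip >= 0; --skip) {
    std::array<int, 3> f;
    int k = 0;
    for (int a = 0; a < 4; ++a)
      if (a != skip) f[k++] = seed[a];
    faces.push_back(f);
    face_active.push_back(true);
  }

  std::vector<bool> placed(n, false);
  for (int s : seed) placed[s] = true;
  std::vector<int> unplaced;
  for (int i = 0; i < n; ++i)
    if (!placed[i]) unplaced.push_back(i);

  // gain[v][f]: similarity of v to face f's three corners
  std::vector<std::vector<double>> gain(n);
  for (int v : unplaced) {
    gain[v].reserve(max_faces);
    for (size_t f = 0; f < faces.size(); ++f)
      gain[v].push_back(w(v, faces[f][0]) + w(v, faces[f][1]) +
                        w(v, faces[f][2]));
  }

  while (!unplaced.empty()) {
    int best_v = -1, best_f = -1;
    double best_g = -1.0;
    for (int v : unplaced) {             // ascending: lowest index wins ties
      const std::vector<double>& gv = gain[v];
      for (size_t f = 0; f < gv.size(); ++f) {
        if (!face_active[f]) continue;
        if (gv[f] > best_g) {            // strict: earliest face wins ties
          best_g = gv[f];
          best_v = v;
          best_f = (int)f;
        }
      }
    }
    std::array<int, 3> tri = faces[best_f];
    for (int k = 0; k < 3; ++k) {
      int a = std::min(best_v, tri[k]), b = std::max(best_v, tri[k]);
      edges(ne, 0) = a + 1;
      edges(ne, 1) = b + 1;
      ++ne;
    }
    face_active[best_f] = false;
    placed[best_v] = true;
    unplaced.erase(std::find(unplaced.begin(), unplaced.end(), best_v));
    for (int k = 0; k < 3; ++k) {
      std::array<int, 3> nf;
      int kk = 0;
      for (int a = 0; a < 3; ++a)
        if (a != k) nf[kk++] = tri[a];
      nf[2] = best_v;
      std::sort(nf.begin(), nf.end());
      faces.push_back(nf);
      face_active.push_back(true);
      for (int v : unplaced)
        gain[v].push_back(w(v, nf[0]) + w(v, nf[1]) + w(v, nf[2]));
    }
  }

  // surviving faces = the 2n-4 triangles of the planar triangulation
  int n_act = 0;
  for (bool a : face_active)
    if (a) ++n_act;
  IntegerMatrix out_faces(n_act, 3);
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!face_active[f]) continue;
    for (int k = 0; k < 3; ++k) out_faces(r, k) = faces[f][k] + 1;
    ++r;
  }
  IntegerVector seed_out(4);
  for (int k = 0; k < 4; ++k) seed_out[k] = seed[k] + 1;

  return List::create(_["edges"] = edges, _["faces"] = out_faces,
                      _["seed"] = seed_out);
}
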