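#include <Rcpp.h>
using namespace Rcpp;

// Breadth-first all-pairs hop distances on an undirected 0/1 adjacency
// matrix. Disconnected pairs are +Inf, the diagonal is 0.
// [[Rcpp::export]]
NumericMatrix bfs_distances(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  const int* A = adj.begin();  // column-major, symmetric
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  // CSR-style neighbor lists
  std::vector<int> deg(n, 0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (A[i + n * j]) ++deg[j];
  std::vector<int> start(n + 1, 0);
  for (int j = 0; j < n; ++j) start[j + 1] = start[j] + deg[j];
  std::vector<int> nbr(start[n]);
  {
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (A[i + n * j]) nbr[pos[j]++] = i;
  }
  std::vector<int> queue(n);
  for (int s = 0; s < n; ++s) {
    double* Ds = &D(0, s);
    Ds[s] = 0.0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      for (int k = start[v]; k < start[v + 1]; ++k) {
        int u = nbr[k];
        if (Ds[u] == R_PosInf) {
          Ds[u] = Ds[v] + 1.0;
          queue[tail++] = u;
        }
      }
    }
  }
  return D;
}

// Nodal local efficiency of a binary graph: the global efficiency of the
// subgraph induced by each node's neighbors (the node itself excluded).
// Paths are constrained to that induced subgraph. Nodes with degree < 2
// score 0, the convention that keeps the mean defined on sparse graphs.
// [[Rcpp::export]]
NumericVector local_efficiency_nodal(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  const int* A = adj.begin();
  NumericVector out(n);
  std::vector<int> nb(n);
  // bitset rows of the induced subgraph; level-synchronous BFS expands a
  // whole frontier with word-parallel OR/AND, which pays off on the dense
  // graphs produced by lenient thresholds
  const int maxWords = (n + 63) / 64;
  std::vector<uint64_t> rows((size_t) n * maxWords);
  std::vector<uint64_t> visited(maxWords), frontier(maxWords), next(maxWords);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    const int* Ai = A + (size_t) n * i;  // column i == row i by symmetry
    for (int j = 0; j < n; ++j)
      if (Ai[j]) nb[m++] = j;
    if (m < 2) { out[i] = 0.0; continue; }
    const int words = (m + 63) / 64;
    std::fill(rows.begin(), rows.begin() + (size_t) m * words, 0ULL);
    for (int a = 0; a < m; ++a) {
      const int* Aa = A + (size_t) n * nb[a];
      uint64_t* row = &rows[(size_t) a * words];
      for (int b = 0; b < m; ++b)
        if (Aa[nb[b]]) row[b >> 6] |= (1ULL << (b & 63));
    }
    double acc = 0.0;
    for (int s = 0; s < m; ++s) {
      std::fill(visited.begin(), visited.begin() + words, 0ULL);
      std::fill(frontier.begin(), frontier.begin() + words, 0ULL);
      visited[s >> 6] = frontier[s >> 6] = (1ULL << (s & 63));
      int d = 0;
      bool alive = true;
      while (alive) {
        ++d;
        std::fill(next.begin(), next.begin() + words, 0ULL);
        for (int w = 0; w < words; ++w) {
          uint64_t bits = frontier[w];
          while (bits) {
            int v = (w << 6) + __builtin_ctzll(bits);
            bits &= bits - 1;
            const uint64_t* row = &rows[(size_t) v * words];
            for (int u = 0; u < words; ++u) next[u] |= row[u];
          }
        }
        alive = false;
        int reached = 0;
        for (int w = 0; w < words; ++w) {
          next[w] &= ~visited[w];
          if (next[w]) alive = true;
          reached += __builtin_popcountll(next[w]);
          visited[w] |= next[w];
          frontier[w] = next[w];
        }
        acc += (double) reached / d;
      }
    }
    out[i] = acc / ((double) m * (m - 1));
  }
  return out;
}
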