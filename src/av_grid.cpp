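// Grid-based accessible-volume core.
//
// Candidate dye positions are grid points within the linker length R of the
// attachment atom.  A point is allowed iff (a) a dye sphere centred there
// clears every protein atom (atom vdW + dye radius) and (b) the point is
// linker-reachable: connected to the attachment through grid cells with
// linker-width clearance by a 26-connected path (Dijkstra, chamfer edge
// weights) of accumulated length <= R.  Cells within 4 A of the attachment
// are always passable -- the linker emerges from the attachment atom and
// must be able to thread past the attachment residue's own atoms.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List av_grid_cpp(NumericVector attachment, NumericMatrix atom_xyz,
                 NumericVector atom_r, double linker_length,
                 double linker_width, double dye_radius, double spacing,
                 bool return_points = false) {
  const int half = (int)std::ceil(linker_length / spacing);
  const int k = 2 * half + 1;
  const long ncell = (long)k * k * k;
  std::vector<char> dye_block(ncell, 0), link_block(ncell, 0);
  const double x0 = attachment[0] - half * spacing;
  const double y0 = attachment[1] - half * spacing;
  const double z0 = attachment[2] - half * spacing;

  // mark blocked cells atom by atom (local bounding boxes)
  const int natom = atom_xyz.nrow();
  const double link_clear = linker_width / 2.0;
  for (int a = 0; a < natom; ++a) {
    const double ax = atom_xyz(a, 0), ay = atom_xyz(a, 1), az = atom_xyz(a, 2);
    const double rd = atom_r[a] + dye_radius;   // dye-clash radius
    const double rl = atom_r[a] + link_clear;   // linker-clash radius
    const double rmax = std::max(rd, rl);
    int ilo = (int)std::floor((ax - rmax - x0) / spacing);
    int ihi = (int)std::ceil((ax + rmax - x0) / spacing);
    int jlo = (int)std::floor((ay - rmax - y0) / spacing);
    int jhi = (int)std::ceil((ay + rmax - y0) / spacing);
    int llo = (int)std::floor((az - rmax - z0) / spacing);
    int lhi = (int)std::ceil((az + rmax - z0) / spacing);
    if (ihi < 0 || ilo >= k || jhi < 0 || jlo >= k || lhi < 0 || llo >= k)
      continue;
    ilo = std::max(ilo, 0); ihi = std::min(ihi, k - 1);
    jlo = std::max(jlo, 0); jhi = std::min(jhi, k - 1);
    llo = std::max(llo, 0); lhi = std::min(lhi, k - 1);
    const double rd2 = rd * rd, rl2 = rl * rl;
    for (int i = ilo; i <= ihi; ++i) {
      const double dx = x0 + i * spacing - ax;
      for (int j = jlo; j <= jhi; ++j) {
        const double dy = y0 + j * spacing - ay;
        const double dxy2 = dx * dx + dy * dy;
        if (dxy2 > rmax * rmax) continue;
        for (int l = llo; l <= lhi; ++l) {
          const double dz = z0 + l * spacing - az;
          const double d2 = dxy2 + dz * dz;
          if (d2 >= rd2 && d2 >= rl2) continue;
          const long idx = ((long)i * k + j) * k + l;
          if (d2 < rd2) dye_block[idx] = 1;
          if (d2 < rl2) link_block[idx] = 1;
        }
      }
    }
  }

  // seed clearance: cells within 4 A of the attachment are passable
  const double seed_clear = 4.0;
  {
    const int s = (int)std::ceil(seed_clear / spacing);
    for (int i = half - s; i <= half + s; ++i)
      for (int j = half - s; j <= half + s; ++j)
        for (int l = half - s; l <= half + s; ++l) {
          if (i < 0 || i >= k || j < 0 || j >= k || l < 0 || l >= k) continue;
          const double dd = ((double)(i - half) * (i - half) +
                             (double)(j - half) * (j - half) +
                             (double)(l - half) * (l - half)) *
                            spacing * spacing;
          if (dd <= seed_clear * seed_clear)
            link_block[((long)i * k + j) * k + l] = 0;
        }
  }

  // Dijkstra over passable cells.  Neighbourhood: all offsets in the
  // 5x5x5 block with coprime components, so grid path lengths track the
  // Euclidean geodesic to ~3% (blocked regions are several cells thick at
  // typical clash radii, so multi-cell steps cannot tunnel through them).
  std::vector<int> oi, oj, ol;
  std::vector<float> ow;
  for (int mi = -2; mi <= 2; ++mi)
    for (int mj = -2; mj <= 2; ++mj)
      for (int ml = -2; ml <= 2; ++ml) {
        if (!mi && !mj && !ml) continue;
        int g = 0;
        const int a[3] = {std::abs(mi), std::abs(mj), std::abs(ml)};
        for (int t = 0; t < 3; ++t)
          for (int d = 2; d >= 1; --d)
            if (a[t] && a[t] % d == 0 &&
                (!a[0] || a[0] % d == 0) && (!a[1] || a[1] % d == 0) &&
                (!a[2] || a[2] % d == 0)) { g = std::max(g, d); }
        if (g == 2) continue;  // multiple of a shorter offset
        oi.push_back(mi); oj.push_back(mj); ol.push_back(ml);
        // chamfer weights slightly rescaled so the discrete metric brackets
        // the Euclidean geodesic instead of always overestimating it
        ow.push_back((float)(0.9862 * spacing *
          std::sqrt((double)(mi * mi + mj * mj + ml * ml))));
      }
  const int noff = (int)oi.size();
  std::vector<float> dist(ncell, -1.0f);
  typedef std::pair<float, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  const long start = ((long)half * k + half) * k + half;
  dist[start] = 0.0f;
  pq.push(Node(0.0f, start));
  while (!pq.empty()) {
    const Node nd = pq.top(); pq.pop();
    const long c = nd.second;
    if (nd.first > dist[c] + 1e-6f) continue;
    const int i = (int)(c / ((long)k * k));
    const int j = (int)((c / k) % k);
    const int l = (int)(c % k);
    for (int m = 0; m < noff; ++m) {
      const int ni = i + oi[m], nj = j + oj[m], nl = l + ol[m];
      if (ni < 0 || ni >= k || nj < 0 || nj >= k || nl < 0 || nl >= k)
        continue;
      const long nc = ((long)ni * k + nj) * k + nl;
      if (link_block[nc]) continue;
      const float ndist = dist[c] + ow[m];
      if (ndist > (float)linker_length) continue;
      if (dist[nc] < 0.0f || ndist < dist[nc] - 1e-6f) {
        dist[nc] = ndist;
        pq.push(Node(ndist, nc));
      }
    }
  }

  // collect allowed dye positions
  const double R2 = linker_length * linker_length;
  double sx = 0, sy = 0, sz = 0;
  long nallow = 0;
  std::vector<double> px, py, pz;
  for (int i = 0; i < k; ++i) {
    const double cx = x0 + i * spacing;
    for (int j = 0; j < k; ++j) {
      const double cy = y0 + j * spacing;
      for (int l = 0; l < k; ++l) {
        const long idx = ((long)i * k + j) * k + l;
        if (dye_block[idx] || dist[idx] < 0.0f) continue;
        const double cz = z0 + l * spacing;
        const double dx = cx - attachment[0], dy = cy - attachment[1],
                     dz = cz - attachment[2];
        if (dx * dx + dy * dy + dz * dz > R2) continue;
        sx += cx; sy += cy; sz += cz;
        ++nallow;
        if (return_points) { px.push_back(cx); py.push_back(cy); pz.push_back(cz); }
      }
    }
  }

  NumericVector mean_pos(3, NA_REAL);
  if (nallow > 0) {
    mean_pos[0] = sx / nallow;
    mean_pos[1] = sy / nallow;
    mean_pos[2] = sz / nallow;
  }
  List out = List::create(_["mean_position"] = mean_pos,
                          _["n_points"] = (double)nallow);
  if (return_points) {
    NumericMatrix pts(nallow, 3);
    for (long p = 0; p < nallow; ++p) {
      pts(p, 0) = px[p]; pts(p, 1) = py[p]; pts(p, 2) = pz[p];
    }
    out["points"] = pts;
  }
  return out;
}
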