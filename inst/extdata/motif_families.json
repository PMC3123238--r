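[
  {"family": "f1", "role": "core", "n": 3, "identifier": "211-12-12",
   "edges": [[1,2],[2,3]],
   "note": "open linear chain"},
  {"family": "f2", "role": "core", "n": 3, "identifier": "222-222-222",
   "edges": [[1,2],[1,3],[2,3]],
   "note": "closed triplet clique"},
  {"family": "f3a", "role": "core", "n": 4, "identifier": "222-222-222-222",
   "edges": [[1,2],[2,3],[3,4],[4,1]],
   "note": "closed four-ring, no diagonal"},
  {"family": "f3b", "role": "core", "n": 4, "identifier": "3322-3322-233-233",
   "edges": [[1,2],[2,3],[3,4],[4,1],[1,3]],
   "note": "closed four-ring with one diagonal"},
  {"family": "f4a", "role": "core", "n": 5, "identifier": "222-222-222-222-222",
   "edges": [[1,2],[2,3],[3,4],[4,5],[5,1]],
   "note": "closed five-ring, no diagonal"},
  {"family": "f4b", "role": "core", "n": 5, "identifier": "3322-3322-233-232-232",
   "edges": [[1,2],[2,3],[3,4],[4,5],[5,1],[1,3]],
   "note": "closed five-ring with one diagonal"},
  {"family": "f4c", "role": "core", "n": 6, "identifier": "222-222-222-222-222-222",
   "edges": [[1,2],[2,3],[3,4],[4,5],[5,6],[6,1]],
   "note": "closed six-ring"},
  {"family": "f4c", "role": "core", "n": 6, "identifier": "3322-3322-233-232-232-222",
   "edges": [[1,2],[2,3],[3,4],[4,5],[5,6],[6,1],[1,3]],
   "note": "closed six-ring, short diagonal"},
  {"family": "f4c", "role": "core", "n": 6, "identifier": "3322-3322-232-232-232-232",
   "edges": [[1,2],[2,3],[3,4],[4,5],[5,6],[6,1],[1,4]],
   "note": "closed six-ring, long diagonal"},
  {"family": "f5", "role": "core", "n": 5, "identifier": "43322-3432-3432-243-243",
   "edges": [[1,2],[1,3],[2,3],[2,4],[3,4],[3,5],[4,5]],
   "note": "strip of three edge-fused triplet cliques"},
  {"family": "f6a", "role": "core", "n": 5, "identifier": "42222-242-242-242-242",
   "edges": [[1,2],[1,3],[2,3],[1,4],[1,5],[4,5]],
   "note": "two triplet cliques sharing a node"},
  {"family": "f6b", "role": "core", "n": 6, "identifier": "3322-3322-232-232-232-232",
   "edges": [[1,2],[1,3],[2,3],[3,4],[4,5],[4,6],[5,6]],
   "note": "two triplet cliques connected by an edge"},
  {"family": "f7", "role": "core", "n": 7, "identifier": "42222-242-242-242-242-222-222",
   "edges": [[1,2],[2,3],[3,4],[4,1],[1,5],[5,6],[6,7],[7,1]],
   "note": "two four-rings sharing a node"},
  {"family": "f8a", "role": "core", "n": 5, "identifier": "43331-3433-3433-3433-14",
   "edges": [[1,2],[1,3],[1,4],[2,3],[2,4],[3,4],[4,5]],
   "note": "embedded quadruplet clique with linear branching"},
  {"family": "f8b", "role": "core", "n": 6, "identifier": "3333-3333-3333-3333-3333-3333",
   "edges": [[1,4],[1,5],[1,6],[2,4],[2,5],[2,6],[3,4],[3,5],[3,6]],
   "note": "non-planar graph without a quadruplet clique (provisional seed)"},
  {"family": "f8c", "role": "core", "n": 5, "identifier": "3222-3222-233-233-233",
   "edges": [[1,3],[2,3],[1,4],[2,4],[1,5],[2,5]],
   "note": "two non-adjacent nodes joined by more than two node sequences (provisional seed)"},
  {"family": "f4a", "role": "exception", "n": 7,
   "identifier": "3332-3322-3321-233-232-232-13",
   "note": "five-ring with a triplet clique fused across two vertices, plus branching; retained in f4a"},
  {"family": "f4b", "role": "exception", "n": 6,
   "identifier": "43322-3432-3432-243-242-232",
   "note": "five-ring (one diagonal) with a fused triplet clique; retained in f4b"},
  {"family": "f4b", "role": "exception", "n": 7,
   "identifier": "533221-3532-3532-253-252-232-15",
   "note": "five-ring (one diagonal) with a fused triplet clique and branching; retained in f4b"},
  {"family": "f4b", "role": "exception", "n": 7,
   "identifier": "44322-44321-3442-244-242-232-14",
   "note": "five-ring (one diagonal) with a fused triplet clique and a pendant; terminal node string corrected from 14 (a degree-1 node attached to a degree-4 node cannot read 12)"}
]
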