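code	band	anatomic_label	applicable_sites
201	locoregional	pericecal nodes	cecum
211	locoregional	paracolic nodes, ascending colon	ascending
221	locoregional	paracolic nodes, transverse colon	transverse
231	locoregional	paracolic nodes, descending colon	descending
241	locoregional	paracolic nodes, sigmoid colon	sigmoid
251	locoregional	superior rectal nodes	superior_rectum
252	locoregional	middle rectal nodes	middle_rectum
253	locoregional	inferior rectal nodes	inferior_rectum
202	intermediate	ileocolic artery nodes	cecum
212	intermediate	right colic artery nodes	ascending
222	intermediate	middle colic artery nodes	transverse
232	intermediate	left colic artery nodes	descending
242	intermediate	sigmoidal artery nodes	sigmoid
261	intermediate	superior rectal artery trunk nodes	superior_rectum
262	intermediate	middle rectal artery nodes	middle_rectum
263	intermediate	internal iliac nodes	inferior_rectum
203	central	ileocolic artery origin nodes	cecum
213	central	right colic artery origin nodes	ascending
223	central	middle colic artery origin nodes	transverse
233	central	inferior mesenteric artery origin nodes	descending
243	central	inferior mesenteric artery root nodes	sigmoid
271	central	aortic bifurcation nodes	superior_rectum
272	central	lateral pelvic nodes	middle_rectum
273	central	obturator nodes	inferior_rectum
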