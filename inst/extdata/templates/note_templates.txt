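# Clinical-note sentence templates for the synthetic corpus generator.
# Format: "category: sentence". Slots: {SERVICE} = a service phrase,
# {REL} = a relation word. Lines starting with "#" and blanks are ignored.
#
# Filler sentences deliberately avoid military vocabulary AND relation
# words, so that window-based other-person removal cannot clip a genuine
# self-service mention across sentence boundaries.
filler: Patient attended the outpatient clinic today for a scheduled review.
filler: Sleep remains poor with frequent waking and low appetite reported.
filler: Mood described as low with reduced interest in usual activities.
filler: Medication reviewed and dose continued at the current level.
filler: Patient engaged well during the session and maintained eye contact.
filler: Reports occasional anxiety in crowded places such as supermarkets.
filler: No thoughts of self harm expressed at today's appointment.
filler: Community team to follow up by telephone in two weeks.
filler: Patient is currently unemployed and looking for part time work.
filler: Alcohol intake discussed and remains within recommended limits.
filler: Attended with a support worker from the local housing team.
filler: Care plan updated and copied to the general practitioner.
filler: Patient reports feeling somewhat brighter since the last review.
filler: Concentration remains limited but daily routine is improving.
#
# Self-service sentences: the patient's own military history.
self: Patient reports that he {SERVICE} before moving to London.
self: She mentioned during assessment that she {SERVICE} as a young adult.
self: Background history notes the patient {SERVICE} for several years.
self: Patient {SERVICE} and finds it difficult to discuss that period.
self: He stated that he {SERVICE} and left at the end of his engagement.
#
# Service phrases: each contains at least one military lexicon entry.
service_phrase: served in the army
service_phrase: served in the navy
service_phrase: served in the forces
service_phrase: is a veteran of the armed forces
service_phrase: was a soldier in an infantry regiment
service_phrase: completed a tour of duty overseas
service_phrase: did national service
service_phrase: was in the royal air force
service_phrase: was in the royal navy
service_phrase: is ex military
#
# Other-person service sentences: a family member or acquaintance served.
# Their service phrases are kept short so the military term always falls
# within the default 5-token relation window.
other: Patient's {REL} {SERVICE} and this is a recurring topic in sessions.
other: His {REL} {SERVICE} and the anniversary is approaching.
other: Her {REL} {SERVICE} which she speaks about with pride.
other: The patient's {REL} {SERVICE} many years ago.
#
other_service_phrase: served in the army
other_service_phrase: served in the navy
other_service_phrase: served in the forces
other_service_phrase: was in the raf
other_service_phrase: did national service
other_service_phrase: completed a tour of duty
#
# Charity confounder sentences: military vocabulary inside a charity name.
charity: Patient receives support from the Salvation Army food bank each week.
charity: Currently staying at a Salvation Army hostel in the borough.
charity: The Salvation Army has been assisting with clothing and meals.
#
# Metaphor confounder sentences: military wording used figuratively.
metaphor: She organises her medication with military precision every morning.
metaphor: Patient describes battling low mood for most of the winter.
metaphor: He has been soldiering on at work despite poor sleep.
metaphor: An army of volunteers at the day centre has been a great help.
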